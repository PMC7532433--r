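# The dynamic chill-portion model (C9). Chilling is accumulated in two
# steps: cold temperatures build a thermally labile intermediate precursor;
# once the precursor pool reaches a full unit, a temperature-dependent
# fraction is converted irreversibly into a chill portion. Warm spells
# destroy the unconverted pool but never the banked portions. Constants are
# the published set (a0, a1: rate amplitudes; e0, e1: activation energies in
# K; slp, tetmlt: slope and transition temperature, K, of the conversion
# sigmoid). The model is applied at daily resolution, consistent with the
# daily application of every other model in the registry.

.dyn <- list(a0 = 139500, a1 = 2.567e18, e0 = 4153.5, e1 = 12888.8,
             slp = 1.6, tetmlt = 277)

# per-temperature intermediate quantities of the recursion
.dyn_terms <- function(t_mean) {
  p <- .dyn
  TK <- t_mean + 273
  sr <- exp(p$slp * p$tetmlt * (TK - p$tetmlt) / TK)
  list(
    xi = sr / (1 + sr),                    # conversion fraction at completion
    xs = (p$a0 / p$a1) * exp((p$e1 - p$e0) / TK),  # pool equilibrium level
    ek = exp(-p$a1 * exp(-p$e1 / TK))      # one-day pool relaxation factor
  )
}

#' Fresh state for the dynamic chill-portion model
#'
#' @return A list with components `intermediate_pool` (unconverted precursor,
#'   dimensionless) and `portions` (accumulated chill portions), both zero.
#'   State is reset at each dormancy-season start; portions never decrease.
#' @export
dynamic_chill_state <- function() {
  list(intermediate_pool = 0, portions = 0)
}

#' One daily step of the dynamic chill-portion model (C9)
#'
#' Advances the precursor/portion recursion by one day at the given daily
#' mean temperature. The precursor pool relaxes toward a temperature-dependent
#' equilibrium (high in the cold, near zero in warmth); when the pool reaches
#' one full unit, a fraction `xi` of it is converted to portions and removed
#' from the pool. Sustained warmth (about 30 degrees C and above) drives the
#' pool toward zero without yielding portions.
#'
#' @param state State list as returned by [dynamic_chill_state()] or a
#'   previous step.
#' @param t_mean Daily mean temperature (degrees C), a single finite value.
#' @return A list with components `state` (the advanced state) and
#'   `delta_portions` (the portions gained this day, `>= 0`).
#' @examples
#' st <- dynamic_chill_state()
#' step <- dynamic_chill_step(st, 6)
#' step$delta_portions   # 0: one day cannot complete a portion
#' @export
dynamic_chill_step <- function(state, t_mean) {
  stopifnot(
    is.list(state),
    is.numeric(state$intermediate_pool), state$intermediate_pool >= 0,
    is.numeric(state$portions), state$portions >= 0,
    length(t_mean) == 1L, is.finite(t_mean)
  )
  tr <- .dyn_terms(t_mean)
  x <- tr$xs - (tr$xs - state$intermediate_pool) * tr$ek
  delta <- 0
  if (x >= 1) {
    delta <- tr$xi * x
    x <- x - delta
  }
  list(
    state = list(intermediate_pool = x, portions = state$portions + delta),
    delta_portions = delta
  )
}

#' Cumulative chill portions along a daily temperature path
#'
#' Runs the C9 recursion from a fresh state over a vector of daily mean
#' temperatures and returns the accumulated portions after each day. This is
#' the vectorized workhorse behind [accumulate()] for model `C9`.
#'
#' @param t_mean Numeric vector of daily mean temperatures in date order.
#' @return Numeric vector of the same length: non-decreasing cumulative chill
#'   portions.
#' @export
dynamic_chill_portions <- function(t_mean) {
  stopifnot(is.numeric(t_mean), all(is.finite(t_mean)))
  n <- length(t_mean)
  if (n == 0L) return(numeric(0))
  tr <- .dyn_terms(t_mean)
  xi <- tr$xi; xs <- tr$xs; ek <- tr$ek
  out <- numeric(n)
  x <- 0; tot <- 0
  for (i in seq_len(n)) {
    x <- xs[i] - (xs[i] - x) * ek[i]
    if (x >= 1) {
      d <- xi[i] * x
      tot <- tot + d
      x <- x - d
    }
    out[i] <- tot
  }
  out
}
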