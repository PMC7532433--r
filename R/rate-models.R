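# Registry of daily rate-of-chilling (C1-C12) and rate-of-forcing (F1-F8)
# models. All functions are pure and vectorized over temperature; the only
# stateful model is the dynamic chill-portion model C9 (see dynamic-model.R).

# GDH (F8) cardinal temperatures, degrees C
.gdh_TL <- 4
.gdh_Tu <- 25
.gdh_Tc <- 36

.cu_weibull <- function(t) {
  # Base is floored at 0: the expression is undefined for t in [-4.7, -4.66)
  # (negative base, fractional exponent); the floor gives rate 0 there,
  # matching the limit from above.
  x <- pmax(t + 4.66, 0) / 10.93
  3.13 * x^2.10 * exp(-x^3.10)
}

.chilling_funs <- list(
  C1  = function(t) as.numeric(t <= 5),
  C2  = function(t) as.numeric(t >= -10 & t <= 5),
  C3  = function(t) as.numeric(t >= 0 & t <= 5),
  C4  = function(t) as.numeric(t <= 7),
  C5  = function(t) as.numeric(t >= -10 & t <= 7),
  C6  = function(t) as.numeric(t >= 0 & t <= 7),
  C7  = function(t) {
    ifelse(t <= 1.4, 0,
    ifelse(t <= 2.4, 0.5,
    ifelse(t <= 9.1, 1,
    ifelse(t <= 12.4, 0.5,
    ifelse(t <= 15.9, 0,
    ifelse(t <= 18, -0.5, -1))))))
  },
  C8  = function(t) {
    ifelse(t <= 1.4, 0,
    ifelse(t <= 2.4, 0.5,
    ifelse(t <= 9.1, 1,
    ifelse(t <= 12.4, 0.5, 0))))
  },
  # rate 1 on the open interval (2.5, 7.4); Weibull elsewhere inside
  # [-4.7, 16]; the small discontinuities at 2.5 and 7.4 are as published
  C10 = function(t) {
    ifelse(t > 2.5 & t < 7.4, 1,
    ifelse(t < -4.7 | t > 16, 0, .cu_weibull(t)))
  },
  C11 = function(t) {
    ifelse(t <= -3.4 | t >= 10.4, 0,
    ifelse(t <= 5, (t + 3.4) / (5 + 3.4), (t - 10.4) / (5 - 10.4)))
  },
  C12 = function(t) {
    ifelse(t <= -6.5 | t >= 6.9, 0,
    ifelse(t <= 0.2, (t + 6.5) / (6.9 - 0.2), (6.9 - t) / (6.9 - 0.2)))
  }
)

.forcing_funs <- list(
  F1 = function(t_mean, t_max, t_min) pmax(t_mean, 0),
  F2 = function(t_mean, t_max, t_min) pmax(t_mean - 5, 0),
  F3 = function(t_mean, t_max, t_min) pmax(t_max, 0),
  F4 = function(t_mean, t_max, t_min) pmax(t_max - 5, 0),
  F5 = function(t_mean, t_max, t_min) {
    0.75 * pmax(t_max - 5, 0) + 0.25 * pmax(t_min - 5, 0)
  },
  F6 = function(t_mean, t_max, t_min) {
    ifelse(t_mean > 0, 28.4 / (1 + exp(-0.185 * (t_mean - 18.5))), 0)
  },
  F7 = function(t_mean, t_max, t_min) 1 / (1 + exp(-0.47 * t_mean + 6.49)),
  F8 = function(t_mean, t_max, t_min) {
    TL <- .gdh_TL; Tu <- .gdh_Tu; Tc <- .gdh_Tc
    # middle-branch condition read as TL <= T <= Tu, the only reading under
    # which the three branches partition the temperature axis
    ifelse(t_mean < TL | t_mean > Tc, 0,
    ifelse(t_mean <= Tu,
      (Tu - TL) / 2 * (1 + cos(pi + pi * (t_mean - TL) / (Tu - TL))),
      (Tu - TL) * (1 + cos(pi / 2 + pi / 2 * (t_mean - Tu) / (Tc - Tu)))))
  }
)

.model_params <- list(
  C1  = c(t_upper = 5),
  C2  = c(t_lower = -10, t_upper = 5),
  C3  = c(t_lower = 0, t_upper = 5),
  C4  = c(t_upper = 7),
  C5  = c(t_lower = -10, t_upper = 7),
  C6  = c(t_lower = 0, t_upper = 7),
  C7  = c(t1 = 1.4, t2 = 2.4, t3 = 9.1, t4 = 12.4, t5 = 15.9, t6 = 18),
  C8  = c(t1 = 1.4, t2 = 2.4, t3 = 9.1, t4 = 12.4),
  C9  = c(a0 = 139500, a1 = 2.567e18, e0 = 4153.5, e1 = 12888.8,
          slp = 1.6, tetmlt = 277),
  C10 = c(shift = 4.66, scale = 10.93, shape1 = 2.10, shape2 = 3.10,
          amp = 3.13, lo = -4.7, hi = 16, plateau_lo = 2.5,
          plateau_hi = 7.4),
  C11 = c(t_min = -3.4, t_opt = 5, t_max = 10.4),
  C12 = c(t_min = -6.5, t_opt = 0.2, t_max = 6.9),
  F1  = c(threshold = 0),
  F2  = c(threshold = 5),
  F3  = c(threshold = 0),
  F4  = c(threshold = 5),
  F5  = c(threshold = 5, w_day = 0.75, w_night = 0.25),
  F6  = c(scale = 28.4, rate = 0.185, midpoint = 18.5),
  F7  = c(rate = 0.47, offset = 6.49),
  F8  = c(t_lower = .gdh_TL, t_opt = .gdh_Tu, t_critical = .gdh_Tc)
)

.chilling_ids <- paste0("C", 1:12)
.forcing_ids <- paste0("F", 1:8)
.all_model_ids <- c(.chilling_ids, .forcing_ids)

.required_inputs <- function(model_id) {
  switch(model_id,
    F3 = "t_max", F4 = "t_max",
    F5 = c("t_max", "t_min"),
    "t_mean"
  )
}

.check_model_id <- function(model_id, allowed = .all_model_ids) {
  if (length(model_id) != 1L || !is.character(model_id) ||
      !model_id %in% allowed) {
    stop("unknown model id: ", paste(model_id, collapse = ", "),
         " (expected one of ", paste(allowed, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(model_id)
}

#' Daily rate of chilling for a stateless chilling model
#'
#' Evaluates the daily rate-of-chilling function of one of the eleven
#' stateless chilling models (`C1`--`C8`, `C10`--`C12`) at daily mean
#' temperature. Models `C1`--`C6` are unit-step threshold models with various
#' lower/upper limits; `C7` is the Utah model (with negative weights above
#' 15.9 degrees C); `C8` is the Utah model with the negative weights removed;
#' `C10` is a Weibull-shaped rate with a unit plateau; `C11` and `C12` are
#' triangular rates (optimum 5 and 0.2 degrees C respectively).
#'
#' The dynamic chill-portion model `C9` carries state between days and must
#' be evaluated with [dynamic_chill_step()] (or via [accumulate()], which
#' manages the state); passing `"C9"` here is an error.
#'
#' @param model_id Chilling model id, one of `"C1"`..`"C8"`, `"C10"`..`"C12"`.
#' @param t_mean Numeric vector of daily mean temperatures (degrees C).
#' @return Numeric vector of daily chilling rates (chill units per day).
#'   All rates lie in `[0, 1]` except `C7`, which lies in `[-1, 1]`.
#' @examples
#' chilling_rate("C1", c(3, 6))    # 1, 0
#' chilling_rate("C12", 0.2)       # triangular optimum, rate 1
#' @export
chilling_rate <- function(model_id, t_mean) {
  .check_model_id(model_id, .chilling_ids)
  if (model_id == "C9") {
    stop("C9 is the stateful dynamic model; use dynamic_chill_step() or ",
         "accumulate(), which reset and carry its state", call. = FALSE)
  }
  stopifnot(is.numeric(t_mean), all(is.finite(t_mean)))
  .chilling_funs[[model_id]](t_mean)
}

#' Daily rate of forcing
#'
#' Evaluates the daily rate-of-forcing function of models `F1`--`F8`.
#' `F1`/`F2` are growing-degree-day rates of daily mean temperature above 0
#' and 5 degrees C; `F3`/`F4` use daily maximum temperature instead; `F5`
#' weights daytime (maximum, weight 0.75) and nighttime (minimum, weight
#' 0.25) degrees above 5; `F6` and `F7` are logistic rates of mean
#' temperature; `F8` is a growing-degree-hour style cosine response applied
#' at daily resolution with cardinal temperatures 4, 25 and 36 degrees C.
#'
#' @param model_id Forcing model id, one of `"F1"`..`"F8"`.
#' @param t_mean Daily mean temperature (degrees C). Required by all models
#'   except `F3`, `F4` and `F5`.
#' @param t_max Daily maximum temperature; required by `F3`, `F4` and `F5`.
#' @param t_min Daily minimum temperature; required by `F5`.
#' @return Numeric vector of daily forcing rates (forcing units per day),
#'   always non-negative.
#' @examples
#' forcing_rate("F1", t_mean = 10)                 # 10
#' forcing_rate("F5", t_max = 15, t_min = 3)       # 7.5
#' @export
forcing_rate <- function(model_id, t_mean = NULL, t_max = NULL, t_min = NULL) {
  .check_model_id(model_id, .forcing_ids)
  need <- .required_inputs(model_id)
  supplied <- list(t_mean = t_mean, t_max = t_max, t_min = t_min)
  for (nm in need) {
    if (is.null(supplied[[nm]])) {
      stop("forcing model ", model_id, " requires input ", nm, call. = FALSE)
    }
    if (!all(is.finite(supplied[[nm]]))) {
      stop("non-finite values in ", nm, call. = FALSE)
    }
  }
  .forcing_funs[[model_id]](t_mean, t_max, t_min)
}

#' List all registered rate models
#'
#' Returns the model registry as a data frame with one row per model in fixed
#' order `C1`..`C12`, `F1`..`F8`. The `params` column serializes each model's
#' constants as `name=value` pairs, so the table can be written directly to
#' CSV as a machine-readable model description.
#'
#' @return A data frame with columns `model_id`, `kind` (`"chilling"` or
#'   `"forcing"`), `stateful` (logical, `TRUE` only for `C9`),
#'   `required_inputs` (comma-separated) and `params`.
#' @examples
#' models <- list_models()
#' nrow(models)                       # 20
#' models$model_id[models$stateful]   # "C9"
#' @export
list_models <- function() {
  ids <- .all_model_ids
  data.frame(
    model_id = ids,
    kind = ifelse(ids %in% .chilling_ids, "chilling", "forcing"),
    stateful = ids == "C9",
    required_inputs = vapply(
      ids, function(id) paste(.required_inputs(id), collapse = ","), ""
    ),
    params = vapply(
      ids,
      function(id) {
        p <- .model_params[[id]]
        paste(sprintf("%s=%g", names(p), p), collapse = ";")
      },
      ""
    ),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Export the model registry to CSV
#'
#' @param path Output file path.
#' @return Invisibly, the table written (see [list_models()]).
#' @export
export_model_table <- function(path) {
  tab <- list_models()
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

# Internal: daily rate series for any model id over a series window.
# For C9 this is the per-day portion increments (fresh state at the start).
.rate_series <- function(model_id, t_mean, t_max = NULL, t_min = NULL) {
  if (model_id %in% .forcing_ids) {
    forcing_rate(model_id, t_mean = t_mean, t_max = t_max, t_min = t_min)
  } else if (model_id == "C9") {
    diff(c(0, dynamic_chill_portions(t_mean)))
  } else {
    chilling_rate(model_id, t_mean)
  }
}
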