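# Per-station linear trends in chilling accumulation and inter-model
# correlation of CA series.

#' Linear trend of an annual series
#'
#' Ordinary least-squares regression of `values` on `years`. The p-value is
#' from the regression F-test of zero slope, which for a single predictor is
#' identical to the two-sided t-test on the slope.
#'
#' @param years Numeric vector of years (distinct, length >= 3).
#' @param values Numeric vector of the same length (e.g., yearly CA).
#' @param alpha Significance level for the trend class; default 0.05.
#' @return A `trend_result` list: `slope` (units/year), `intercept`,
#'   `p_value`, `n_years`, `class` (see [classify_trend()]).
#' @examples
#' linear_trend(2000:2002, c(1, 2, 3))$slope   # 1
#' @export
linear_trend <- function(years, values, alpha = 0.05) {
  stopifnot(length(years) == length(values))
  ok <- is.finite(years) & is.finite(values)
  years <- years[ok]; values <- values[ok]
  if (length(years) < 3 || stats::var(years) == 0) {
    stop("insufficient data: need >= 3 points with distinct years",
         call. = FALSE)
  }
  fit <- stats::lm(values ~ years)
  slope <- unname(stats::coef(fit)[2])
  # residual variance can be exactly zero on synthetic straight lines
  if (all(abs(stats::residuals(fit)) < 1e-12)) {
    p <- if (abs(slope) < 1e-12) 1 else 0
  } else {
    p <- unname(summary(fit)$coefficients[2, 4])
  }
  res <- structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         p_value = p, n_years = length(years), class = NA_character_),
    class = "trend_result"
  )
  res$class <- classify_trend(res, alpha)
  res
}

#' Classify a trend as significant/insignificant negative/positive
#'
#' Four-way classification of a fitted trend: `sig_neg`, `insig_neg`,
#' `sig_pos`, `insig_pos` at level `alpha`. A slope of exactly zero is
#' assigned to `insig_neg` by convention (a tie rule; an exactly zero slope
#' is never significant).
#'
#' @param result A `trend_result` from [linear_trend()], or any list with
#'   `slope` and `p_value`.
#' @param alpha Significance level; default 0.05.
#' @return A character scalar, one of the four classes.
#' @export
classify_trend <- function(result, alpha = 0.05) {
  stopifnot(is.finite(result$slope), is.finite(result$p_value))
  neg <- result$slope <= 0   # slope == 0 ties to the negative side
  sig <- result$p_value < alpha && result$slope != 0
  if (neg) {
    if (sig) "sig_neg" else "insig_neg"
  } else {
    if (sig) "sig_pos" else "insig_pos"
  }
}

#' Pairwise Pearson correlation between chilling models' CA series
#'
#' Given one station's yearly CA under several chilling models, returns the
#' matrix of pairwise Pearson correlations (symmetric, unit diagonal).
#'
#' @param ca_by_model Data frame or matrix, one column per chilling model,
#'   one row per year.
#' @return Correlation matrix with model ids as dimnames.
#' @export
model_intercorrelation <- function(ca_by_model) {
  m <- as.matrix(ca_by_model)
  if (nrow(m) < 3) {
    stop("need >= 3 common years", call. = FALSE)
  }
  stats::cor(m)
}

#' Per-station CA trend table
#'
#' Applies [linear_trend()] to every station and chilling model of a yearly
#' CA table and returns a tidy data frame.
#'
#' @param ca_yearly Data frame with columns `station_id`, `year` and one
#'   `ca_<model>` column per chilling model.
#' @param alpha Significance level.
#' @return Data frame with columns `station_id`, `model_id`, `slope`,
#'   `p_value`, `n_years`, `class`.
#' @export
trend_table <- function(ca_yearly, alpha = 0.05) {
  ca_cols <- grep("^ca_", names(ca_yearly), value = TRUE)
  stopifnot(length(ca_cols) >= 1)
  res <- list()
  for (st in split(ca_yearly, ca_yearly$station_id)) {
    for (col in ca_cols) {
      tr <- linear_trend(st$year, st[[col]], alpha)
      res[[length(res) + 1]] <- data.frame(
        station_id = st$station_id[1],
        model_id = sub("^ca_", "", col),
        slope = tr$slope, p_value = tr$p_value,
        n_years = tr$n_years, class = tr$class,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, res)
}
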