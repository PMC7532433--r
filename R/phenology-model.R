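# Process-based onset simulation: the heat requirement on any day is a
# linear function of the chilling accumulated so far (HR = a + b * CA, floored
# at 0), and onset is the first day whose heat accumulation strictly exceeds
# that requirement.

#' Fit a CA-HR process model
#'
#' Fits the linear HR(CA) rule on raw CA-HR records (see
#' [fit_ca_hr_regression()]) and packages it with the model and window
#' choices needed for onset simulation.
#'
#' @param records CA-HR table containing `ca_<chilling_model>` and
#'   `hr_<forcing_model>` columns.
#' @param chilling_model,forcing_model Model ids.
#' @param force_start Heat-accumulation start rule: `"jan1"` (default),
#'   `"jan15"` or `"feb1"`. Chilling always starts 1 November of the
#'   previous year.
#' @return A `pheno_model_params` list: `chilling_model`, `forcing_model`,
#'   `a`, `b`, `ci95_a`, `ci95_b`, `force_start`.
#' @export
fit_pheno_model <- function(records, chilling_model = "C1",
                            forcing_model = "F1",
                            force_start = c("jan1", "jan15", "feb1")) {
  force_start <- match.arg(force_start)
  fit <- fit_ca_hr_regression(records, chilling_model, forcing_model)
  structure(
    list(chilling_model = chilling_model, forcing_model = forcing_model,
         a = fit$a, b = fit$b, ci95_a = fit$ci95_a, ci95_b = fit$ci95_b,
         force_start = force_start),
    class = "pheno_model_params"
  )
}

#' Construct process-model parameters directly
#'
#' @param a Intercept of the HR(CA) rule (forcing units).
#' @param b Slope (forcing units per chill unit); negative under the
#'   physiological expectation.
#' @param chilling_model,forcing_model Model ids.
#' @param force_start Heat-accumulation start rule.
#' @return A `pheno_model_params` list.
#' @export
pheno_model_params <- function(a, b, chilling_model = "C1",
                               forcing_model = "F1",
                               force_start = c("jan1", "jan15", "feb1")) {
  force_start <- match.arg(force_start)
  stopifnot(is.finite(a), is.finite(b))
  structure(
    list(chilling_model = chilling_model, forcing_model = forcing_model,
         a = a, b = b, ci95_a = c(NA_real_, NA_real_),
         ci95_b = c(NA_real_, NA_real_), force_start = force_start),
    class = "pheno_model_params"
  )
}

#' Predict the onset day-of-year for one season
#'
#' Runs the daily loop for the dormancy season ending in `year`: chilling
#' accumulates from 1 November of `year - 1`; heat accumulates from the
#' `force_start` date; the required heat on day t is
#' `max(a + b * CA_t, 0)` (a negative requirement is meaningless and floored
#' at zero). Onset is the first day whose heat accumulation is strictly
#' larger than the requirement; exact equality does not trigger. If the
#' requirement is never exceeded by 31 July, `NA` is returned (a sentinel,
#' not an error).
#'
#' @param params A `pheno_model_params` object.
#' @param series A [daily_series()] covering 1 November of `year - 1`
#'   through 31 July of `year`.
#' @param year Event year.
#' @return Integer day-of-year of onset in `year`, or `NA_integer_`.
#' @examples
#' dates <- seq(as.Date("2000-11-01"), as.Date("2001-07-31"), by = "day")
#' ser <- daily_series(dates, rep(10, length(dates)))
#' p <- pheno_model_params(a = 100, b = 0)
#' predict_onset(p, ser, 2001)   # 11: day 10 reaches exactly 100, not larger
#' @export
predict_onset <- function(params, series, year) {
  stopifnot(inherits(params, "pheno_model_params"),
            inherits(series, "daily_series"))
  start <- as.Date(sprintf("%d-11-01", year - 1))
  jan1 <- as.Date(sprintf("%d-01-01", year))
  end <- as.Date(sprintf("%d-07-31", year))
  idx <- .window_idx(series, start, end)
  tm <- series$t_mean[idx]
  tx <- series$t_max[idx]
  tn <- series$t_min[idx]
  if (anyNA(tm)) {
    stop("missing t_mean in simulation window for ",
         attr(series, "location_id"), "/", year, call. = FALSE)
  }
  n_pre <- as.integer(jan1 - start)
  force_off <- switch(params$force_start, jan1 = 0L, jan15 = 14L, feb1 = 31L)
  ca <- cumsum(.rate_series(params$chilling_model, tm))
  fr <- .rate_series(params$forcing_model, tm, tx, tn)
  fr[seq_len(n_pre + force_off)] <- 0
  heat <- cumsum(fr)
  req <- pmax(params$a + params$b * ca, 0)
  hit <- which(heat > req)
  if (!length(hit)) return(NA_integer_)
  onset <- hit[1]
  as.integer(onset - n_pre)
}

#' Simulate an onset series over many years
#'
#' Applies [predict_onset()] to every event year the series covers (a year is
#' simulated when the series spans 1 November of the previous year through
#' 31 July). Deterministic: identical inputs give identical output.
#'
#' @param params A `pheno_model_params` object.
#' @param series A multi-year [daily_series()].
#' @param years Optional integer vector restricting the event years.
#' @return An `onset_series` data frame: `location_id`, `year`, `onset_doy`
#'   (`NA` where the requirement was never met).
#' @export
simulate_series <- function(params, series, years = NULL) {
  d1 <- series$date[1]; d2 <- series$date[nrow(series)]
  all_years <- (as.integer(format(d1, "%Y")) + 1L):as.integer(format(d2, "%Y"))
  ok <- vapply(all_years, function(y) {
    as.Date(sprintf("%d-11-01", y - 1)) >= d1 &&
      as.Date(sprintf("%d-07-31", y)) <= d2
  }, NA)
  all_years <- all_years[ok]
  if (!is.null(years)) all_years <- intersect(all_years, years)
  out <- data.frame(
    location_id = attr(series, "location_id"),
    year = as.integer(all_years),
    onset_doy = vapply(all_years,
                       function(y) predict_onset(params, series, y),
                       integer(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("onset_series", "data.frame")
  out
}

#' Spatial evaluation of simulated mean onset dates
#'
#' Compares per-location simulated and observed mean onset dates across
#' locations: squared Pearson correlation (the OLS R-squared of observed on
#' simulated) and the root-mean-square error in days.
#'
#' @param simulated,observed Numeric vectors (>= 3 locations).
#' @return A list with `r2` and `rmse`.
#' @examples
#' evaluate_spatial(c(100, 110, 120), c(102, 108, 123))$rmse   # 2.3805
#' @export
evaluate_spatial <- function(simulated, observed) {
  if (length(simulated) != length(observed)) {
    stop("length mismatch", call. = FALSE)
  }
  ok <- is.finite(simulated) & is.finite(observed)
  simulated <- simulated[ok]; observed <- observed[ok]
  if (length(simulated) < 3) stop("need >= 3 locations", call. = FALSE)
  list(
    r2 = stats::cor(simulated, observed)^2,
    rmse = sqrt(mean((simulated - observed)^2))
  )
}

#' Trend evaluation of simulated onset series
#'
#' As [evaluate_spatial()], applied to per-location trends
#' (days per year).
#'
#' @param simulated,observed Numeric vectors of per-location trend slopes.
#' @return A list with `r2` and `rmse` (days/year).
#' @export
evaluate_trends <- function(simulated, observed) {
  evaluate_spatial(simulated, observed)
}

#' Centered moving average
#'
#' Centered mean over an odd window; at the series edges the window is
#' truncated to the available years (so the first and last values average
#' fewer points).
#'
#' @param values Numeric vector (yearly values in year order).
#' @param window Odd window width; default 11.
#' @return Numeric vector of the same length.
#' @examples
#' moving_average(c(rep(0, 5), 11, rep(0, 5)))[6]   # 1
#' @export
moving_average <- function(values, window = 11) {
  stopifnot(window %% 2 == 1, window >= 1)
  h <- (window - 1) / 2
  n <- length(values)
  vapply(seq_len(n), function(i) {
    mean(values[max(1, i - h):min(n, i + h)], na.rm = TRUE)
  }, numeric(1))
}

#' Advance in onset between two decades
#'
#' Mean onset of the reference years minus mean onset of the target years;
#' positive values mean the target decade is earlier (an advance).
#'
#' @param onsets An `onset_series` data frame (or any data frame with `year`
#'   and `onset_doy`), possibly spanning several locations.
#' @param ref_years Reference decade years; default 2010:2018 (the
#'   data-trimmed 2010s).
#' @param target_years Target decade years; default 2090:2099.
#' @return Advance in days (positive = earlier onset in the target decade).
#' @export
decadal_advance <- function(onsets, ref_years = 2010:2018,
                            target_years = 2090:2099) {
  ref <- onsets$onset_doy[onsets$year %in% ref_years]
  tgt <- onsets$onset_doy[onsets$year %in% target_years]
  ref <- ref[!is.na(ref)]; tgt <- tgt[!is.na(tgt)]
  if (!length(ref) || !length(tgt)) {
    stop("both decades need at least one simulated onset", call. = FALSE)
  }
  mean(ref) - mean(tgt)
}
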