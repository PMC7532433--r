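# Daily temperature series container and calendar-window accumulation of
# chilling (CA) and forcing (HR) rates.

#' Construct a daily temperature series
#'
#' A `daily_series` is a data frame with one row per calendar day (contiguous,
#' strictly increasing dates) and columns `date`, `t_mean`, `t_max`, `t_min`,
#' carrying station metadata (`location_id`, `lat`, `lon`, `alt`) as
#' attributes. Missing maximum/minimum temperatures may be `NA`; where all
#' three are present, `t_min <= t_mean <= t_max` is enforced.
#'
#' @param dates `Date` vector, contiguous calendar days.
#' @param t_mean Daily mean temperatures (degrees C).
#' @param t_max,t_min Optional daily maximum/minimum temperatures.
#' @param location_id Station identifier.
#' @param lat,lon,alt Station coordinates (degrees N, degrees E, m).
#' @return A `daily_series` object.
#' @export
daily_series <- function(dates, t_mean, t_max = NULL, t_min = NULL,
                         location_id = "loc", lat = NA_real_,
                         lon = NA_real_, alt = NA_real_) {
  dates <- as.Date(dates)
  n <- length(dates)
  stopifnot(n >= 1, length(t_mean) == n)
  if (any(diff(as.integer(dates)) != 1L)) {
    stop("dates must be contiguous calendar days", call. = FALSE)
  }
  if (is.null(t_max)) t_max <- rep(NA_real_, n)
  if (is.null(t_min)) t_min <- rep(NA_real_, n)
  stopifnot(length(t_max) == n, length(t_min) == n)
  ok <- !is.na(t_mean) & !is.na(t_max) & !is.na(t_min)
  if (any(t_min[ok] > t_mean[ok] | t_mean[ok] > t_max[ok])) {
    stop("t_min <= t_mean <= t_max violated", call. = FALSE)
  }
  out <- data.frame(date = dates, t_mean = as.numeric(t_mean),
                    t_max = as.numeric(t_max), t_min = as.numeric(t_min))
  attr(out, "location_id") <- as.character(location_id)
  attr(out, "lat") <- as.numeric(lat)
  attr(out, "lon") <- as.numeric(lon)
  attr(out, "alt") <- as.numeric(alt)
  class(out) <- c("daily_series", "data.frame")
  out
}

# Contiguous-date index arithmetic: rows of [start, end] within the series,
# or an error naming the window if not fully covered.
.window_idx <- function(series, start, end) {
  d1 <- series$date[1]
  i0 <- as.integer(start - d1) + 1L
  i1 <- as.integer(end - d1) + 1L
  if (i0 < 1L || i1 > nrow(series)) {
    stop("series for ", attr(series, "location_id"),
         " does not cover window ", format(start), " .. ", format(end),
         call. = FALSE)
  }
  i0:i1
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf(
    "<daily_series> %s (%.2f N, %.2f E, %.0f m): %d days, %s .. %s\n",
    attr(x, "location_id"), attr(x, "lat"), attr(x, "lon"), attr(x, "alt"),
    nrow(x), format(x$date[1]), format(x$date[nrow(x)])
  ))
  invisible(x)
}

#' Define a dormancy-season accumulation window
#'
#' Windows are closed date intervals tied to a phenological event year.
#' `start_rule = "nov1_prev_year"` starts on 1 November of `event_year - 1`
#' (the conventional onset of endodormancy); `"jan1"`, `"jan15"` and `"feb1"`
#' start in the event year itself (alternative heat-accumulation starts).
#' `end_rule = "apr30"` ends on 30 April of the event year; `"onset_date"`
#' ends on the observed onset day-of-year (`onset_doy`, 1-based in the event
#' year's own calendar).
#'
#' @param start_rule One of `"nov1_prev_year"`, `"jan1"`, `"jan15"`, `"feb1"`.
#' @param end_rule One of `"apr30"`, `"onset_date"`.
#' @param event_year Calendar year of the spring event.
#' @param onset_doy Day-of-year of onset; required when
#'   `end_rule = "onset_date"`.
#' @return A `season_window` list with `start_rule`, `end_rule`, `event_year`,
#'   `onset_doy`.
#' @export
season_window <- function(start_rule = c("nov1_prev_year", "jan1", "jan15",
                                         "feb1"),
                          end_rule = c("apr30", "onset_date"),
                          event_year, onset_doy = NULL) {
  start_rule <- match.arg(start_rule)
  end_rule <- match.arg(end_rule)
  stopifnot(length(event_year) == 1L, event_year == as.integer(event_year))
  if (end_rule == "onset_date") {
    stopifnot(!is.null(onset_doy), length(onset_doy) == 1L,
              onset_doy >= 1, onset_doy <= 366)
  }
  structure(
    list(start_rule = start_rule, end_rule = end_rule,
         event_year = as.integer(event_year),
         onset_doy = if (is.null(onset_doy)) NA_integer_
                     else as.integer(onset_doy)),
    class = "season_window"
  )
}

#' Resolve a season window to calendar dates
#'
#' @param window A [season_window()].
#' @return A list with `start` and `end` dates (inclusive) and `n_days`, the
#'   number of days in the closed interval. An onset earlier than the start
#'   date is an error (empty window).
#' @examples
#' w <- season_window("nov1_prev_year", "apr30", 2001)
#' resolve_window(w)$n_days   # 181
#' @export
resolve_window <- function(window) {
  stopifnot(inherits(window, "season_window"))
  y <- window$event_year
  start <- switch(window$start_rule,
    nov1_prev_year = as.Date(sprintf("%d-11-01", y - 1)),
    jan1 = as.Date(sprintf("%d-01-01", y)),
    jan15 = as.Date(sprintf("%d-01-15", y)),
    feb1 = as.Date(sprintf("%d-02-01", y))
  )
  end <- switch(window$end_rule,
    apr30 = as.Date(sprintf("%d-04-30", y)),
    onset_date = as.Date(sprintf("%d-01-01", y)) + (window$onset_doy - 1L)
  )
  if (end < start) {
    stop("empty window: end date ", format(end), " precedes start date ",
         format(start), call. = FALSE)
  }
  list(start = start, end = end,
       n_days = as.integer(end - start) + 1L)
}

#' Accumulate a rate model over a season window
#'
#' Sums the daily rate of the given chilling or forcing model over the
#' resolved window (a closed date interval) of a [daily_series()]. For the
#' dynamic model `C9` the state is reset at the window start and the value is
#' the chill portions accumulated over the window.
#'
#' Missing data policy: by default any `NA` among the inputs the model needs
#' inside the window is an error; with `na_tol > 0`, up to that fraction of
#' missing days is accepted and treated as rate 0.
#'
#' @param series A [daily_series()] covering the window.
#' @param model_id A model id, `"C1"`..`"C12"` or `"F1"`..`"F8"`.
#' @param window A [season_window()].
#' @param na_tol Tolerated fraction of missing days in `[0, 1]`; default 0.
#' @return An `accumulation_result` list: `value`, `model_id`, `window`,
#'   `n_days`, `n_missing`.
#' @export
accumulate <- function(series, model_id, window, na_tol = 0) {
  stopifnot(inherits(series, "daily_series"))
  .check_model_id(model_id)
  rw <- resolve_window(window)
  idx <- .window_idx(series, rw$start, rw$end)
  need <- if (model_id %in% .forcing_ids) .required_inputs(model_id)
          else "t_mean"
  vals <- lapply(need, function(nm) series[[nm]][idx])
  names(vals) <- need
  miss <- Reduce(`|`, lapply(vals, is.na))
  n_missing <- sum(miss)
  if (n_missing > na_tol * rw$n_days) {
    stop(sprintf(
      "window %s .. %s for %s has %d missing day(s), above tolerance",
      format(rw$start), format(rw$end), attr(series, "location_id"),
      n_missing
    ), call. = FALSE)
  }
  # missing days within tolerance contribute rate 0
  for (nm in need) vals[[nm]][miss] <- NA_real_
  get0_ <- function(nm) if (nm %in% need) vals[[nm]] else NULL
  tm <- get0_("t_mean"); tx <- get0_("t_max"); tn <- get0_("t_min")
  if (any(miss)) {
    keep <- !miss
    rates <- numeric(rw$n_days)
    rates[keep] <- .rate_series(model_id, tm[keep], tx[keep], tn[keep])
  } else {
    rates <- .rate_series(model_id, tm, tx, tn)
  }
  structure(
    list(value = sum(rates), model_id = model_id, window = window,
         n_days = rw$n_days, n_missing = n_missing),
    class = "accumulation_result"
  )
}

#' Chilling accumulation and heat requirement for one phenological record
#'
#' Computes, for a single observed spring event, the chilling accumulation
#' (CA) under each requested chilling model over the window 1 November of the
#' previous year to the onset date, and the heat requirement (HR) under each
#' requested forcing model from `hr_start` (default 1 January) to the onset
#' date.
#'
#' @param record A one-row data frame (or list) with at least `station_id`,
#'   `species`, `bbch`, `year`, `doy`.
#' @param series The station's [daily_series()].
#' @param chilling_ids Character vector of chilling model ids.
#' @param forcing_ids Character vector of forcing model ids.
#' @param hr_start Start rule for heat accumulation: `"jan1"` (default),
#'   `"jan15"` or `"feb1"`.
#' @param na_tol Missing-day tolerance passed to [accumulate()].
#' @return A one-row data frame with the record keys plus columns
#'   `ca_<model>` and `hr_<model>`.
#' @export
ca_hr_for_record <- function(record, series, chilling_ids = .chilling_ids,
                             forcing_ids = "F1",
                             hr_start = c("jan1", "jan15", "feb1"),
                             na_tol = 0) {
  hr_start <- match.arg(hr_start)
  year <- as.integer(record$year)
  doy <- as.integer(record$doy)
  stopifnot(doy >= 1, doy <= 366)
  ca_win <- season_window("nov1_prev_year", "onset_date", year, doy)
  hr_win <- season_window(hr_start, "onset_date", year, doy)
  out <- data.frame(station_id = as.character(record$station_id),
                    species = as.character(record$species),
                    bbch = as.integer(record$bbch),
                    year = year, doy = doy,
                    stringsAsFactors = FALSE)
  for (id in chilling_ids) {
    out[[paste0("ca_", id)]] <-
      tryCatch(accumulate(series, id, ca_win, na_tol)$value,
               error = function(e) {
                 stop("record ", out$station_id, "/", out$species, "/",
                      year, ": ", conditionMessage(e), call. = FALSE)
               })
  }
  for (id in forcing_ids) {
    out[[paste0("hr_", id)]] <-
      tryCatch(accumulate(series, id, hr_win, na_tol)$value,
               error = function(e) {
                 stop("record ", out$station_id, "/", out$species, "/",
                      year, ": ", conditionMessage(e), call. = FALSE)
               })
  }
  out
}

#' CA and HR for a table of phenological records
#'
#' Vectorized companion of [ca_hr_for_record()]: computes per-record CA (each
#' chilling model; window 1 November previous year to onset) and HR (each
#' forcing model; `hr_start` to onset) for all records, grouped by station so
#' each station-season's rate series is evaluated once. Results are exactly
#' equal to looping [ca_hr_for_record()] over rows.
#'
#' @param records Data frame of phenological records with columns
#'   `station_id`, `species`, `bbch`, `year`, `doy`.
#' @param series_list Named list of [daily_series()], names matching
#'   `station_id`.
#' @param chilling_ids,forcing_ids,hr_start,na_tol As [ca_hr_for_record()].
#' @return A data frame with one row per record: record keys plus `ca_<id>`
#'   and `hr_<id>` columns.
#' @export
cahr_table <- function(records, series_list, chilling_ids = .chilling_ids,
                       forcing_ids = "F1",
                       hr_start = c("jan1", "jan15", "feb1"), na_tol = 0) {
  hr_start <- match.arg(hr_start)
  stopifnot(is.data.frame(records),
            all(c("station_id", "species", "bbch", "year", "doy") %in%
                names(records)))
  missing_st <- setdiff(unique(records$station_id), names(series_list))
  if (length(missing_st)) {
    stop("no temperature series for station(s): ",
         paste(missing_st, collapse = ", "), call. = FALSE)
  }
  hr_off <- switch(hr_start, jan1 = 0L, jan15 = 14L, feb1 = 31L)
  out_ca <- matrix(NA_real_, nrow(records), length(chilling_ids),
                   dimnames = list(NULL, paste0("ca_", chilling_ids)))
  out_hr <- matrix(NA_real_, nrow(records), length(forcing_ids),
                   dimnames = list(NULL, paste0("hr_", forcing_ids)))
  key <- paste(records$station_id, records$year)
  for (grp in split(seq_len(nrow(records)), key)) {
    st <- records$station_id[grp[1]]
    y <- records$year[grp[1]]
    ser <- series_list[[st]]
    start <- as.Date(sprintf("%d-11-01", y - 1))
    jan1 <- as.Date(sprintf("%d-01-01", y))
    max_doy <- max(records$doy[grp])
    end <- jan1 + (max_doy - 1L)
    idx <- .window_idx(ser, start, end)
    tm <- ser$t_mean[idx]; tx <- ser$t_max[idx]; tn <- ser$t_min[idx]
    if (anyNA(tm) && na_tol == 0) {
      stop("missing t_mean in window for ", st, "/", y, call. = FALSE)
    }
    n_pre <- as.integer(jan1 - start)  # days before 1 Jan
    onset_idx <- n_pre + records$doy[grp]
    for (ci in seq_along(chilling_ids)) {
      cs <- cumsum(.rate_series(chilling_ids[ci], tm))
      out_ca[grp, ci] <- cs[onset_idx]
    }
    for (fi in seq_along(forcing_ids)) {
      r <- .rate_series(forcing_ids[fi], tm, tx, tn)
      r[seq_len(n_pre + hr_off)] <- 0
      cs <- cumsum(r)
      if (any(records$doy[grp] <= hr_off)) {
        stop("onset precedes heat-accumulation start for ", st, "/", y,
             call. = FALSE)
      }
      out_hr[grp, fi] <- cs[onset_idx]
    }
  }
  cbind(
    records[c("station_id", "species", "bbch", "year", "doy")],
    as.data.frame(out_ca), as.data.frame(out_hr)
  )
}
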