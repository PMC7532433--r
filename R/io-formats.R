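# Readers/writers for the pipeline's plain-text formats and the
# phenology-to-meteorology station matching rule.

.allowed_bbch <- c(10L, 11L, 60L, 69L)

#' Read phenological records from CSV
#'
#' Expects a header `station_id, species, bbch, year, doy`. Rows with a BBCH
#' stage outside the supported set (10, 11, 60, 69: first leaves separated,
#' first leaves unfolded, first flowers open, end of flowering) or a
#' day-of-year outside 1..366 are rejected, not coerced; the number of
#' rejected rows is reported in the `n_rejected` attribute.
#'
#' @param path CSV file path.
#' @return Data frame of valid records with attribute `n_rejected`.
#' @export
read_phenology <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("station_id", "species", "bbch", "year", "doy")
  if (!all(need %in% names(raw))) {
    stop("phenology CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  raw$bbch <- suppressWarnings(as.integer(raw$bbch))
  raw$year <- suppressWarnings(as.integer(raw$year))
  raw$doy <- suppressWarnings(as.integer(raw$doy))
  ok <- !is.na(raw$bbch) & raw$bbch %in% .allowed_bbch &
    !is.na(raw$year) & !is.na(raw$doy) & raw$doy >= 1 & raw$doy <= 366
  out <- raw[ok, need, drop = FALSE]
  rownames(out) <- NULL
  out$station_id <- as.character(out$station_id)
  out$species <- as.character(out$species)
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Write phenological records to CSV
#'
#' Round-trip identity with [read_phenology()] for valid records.
#'
#' @param records Data frame with `station_id`, `species`, `bbch`, `year`,
#'   `doy`.
#' @param path Output path.
#' @return Invisibly, `records`.
#' @export
write_phenology <- function(records, path) {
  utils::write.csv(
    records[c("station_id", "species", "bbch", "year", "doy")],
    path, row.names = FALSE
  )
  invisible(records)
}

#' Read a station temperature CSV
#'
#' Expects columns `date` (ISO-8601), `tmean` and optionally `tmax`, `tmin`.
#' Dates must be contiguous.
#'
#' @param path CSV file path.
#' @param location_id,lat,lon,alt Station metadata attached to the series.
#' @return A [daily_series()].
#' @export
read_temperature <- function(path, location_id = "loc", lat = NA_real_,
                             lon = NA_real_, alt = NA_real_) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("date", "tmean") %in% names(raw))) {
    stop("temperature CSV must have columns date, tmean", call. = FALSE)
  }
  daily_series(
    as.Date(raw$date), raw$tmean,
    t_max = if ("tmax" %in% names(raw)) raw$tmax else NULL,
    t_min = if ("tmin" %in% names(raw)) raw$tmin else NULL,
    location_id = location_id, lat = lat, lon = lon, alt = alt
  )
}

#' Write a daily series to a station temperature CSV
#'
#' @param series A [daily_series()].
#' @param path Output path.
#' @return Invisibly, `series`.
#' @export
write_temperature <- function(series, path) {
  utils::write.csv(
    data.frame(date = format(series$date), tmean = series$t_mean,
               tmax = series$t_max, tmin = series$t_min),
    path, row.names = FALSE
  )
  invisible(series)
}

#' Read a gridded temperature table and extract the nearest cell
#'
#' The grid is a long-format text table with CF-like coordinates: columns
#' `date`, `lat`, `lon`, `tmean` and optionally `tmax`, `tmin`, one row per
#' cell-day. The cell nearest to the query point by great-circle distance is
#' extracted as a station-like series; ties break deterministically toward
#' the lower cell index (file order).
#'
#' @param path CSV file path.
#' @param lat,lon Query coordinates (degrees).
#' @param location_id Identifier for the extracted series.
#' @return A [daily_series()] for the nearest cell, with the cell's
#'   coordinates as metadata.
#' @export
read_temperature_grid <- function(path, lat, lon, location_id = "cell") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("date", "lat", "lon", "tmean")
  if (!all(need %in% names(raw))) {
    stop("grid CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cells <- unique(raw[c("lat", "lon")])
  d <- haversine_km(lat, lon, cells$lat, cells$lon)
  pick <- cells[which.min(d), ]  # which.min takes the first (lowest index)
  sel <- raw$lat == pick$lat & raw$lon == pick$lon
  sub <- raw[sel, , drop = FALSE]
  sub <- sub[order(as.Date(sub$date)), , drop = FALSE]
  daily_series(
    as.Date(sub$date), sub$tmean,
    t_max = if ("tmax" %in% names(sub)) sub$tmax else NULL,
    t_min = if ("tmin" %in% names(sub)) sub$tmin else NULL,
    location_id = location_id, lat = pick$lat, lon = pick$lon
  )
}

#' Great-circle distance (haversine, spherical Earth)
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees; vectors recycle.
#' @return Distance in km (Earth radius 6371 km).
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(sqrt(a), 1))
}

#' Match phenological stations to meteorological stations
#'
#' Each phenological station is matched to the nearest meteorological station
#' that satisfies both strict thresholds: great-circle distance strictly less
#' than `max_dist` km and altitude difference strictly less than
#' `max_alt_diff` m. Stations with no qualifying neighbour are unmatched.
#'
#' @param pheno,met Station tables with `station_id`, `lat`, `lon`, `alt`.
#' @param max_dist Distance threshold (km); default 5.
#' @param max_alt_diff Altitude threshold (m); default 100.
#' @return Data frame with one row per phenological station: `station_id`,
#'   `met_id` (`NA` if unmatched), `dist_km`, `alt_diff_m`.
#' @export
match_stations <- function(pheno, met, max_dist = 5, max_alt_diff = 100) {
  stopifnot(all(c("station_id", "lat", "lon", "alt") %in% names(pheno)),
            all(c("station_id", "lat", "lon", "alt") %in% names(met)),
            all(abs(pheno$lat) <= 90), all(abs(met$lat) <= 90),
            all(abs(pheno$lon) <= 180), all(abs(met$lon) <= 180))
  out <- lapply(seq_len(nrow(pheno)), function(i) {
    d <- haversine_km(pheno$lat[i], pheno$lon[i], met$lat, met$lon)
    dz <- abs(pheno$alt[i] - met$alt)
    eligible <- d < max_dist & dz < max_alt_diff
    if (!any(eligible)) {
      data.frame(station_id = pheno$station_id[i], met_id = NA_character_,
                 dist_km = NA_real_, alt_diff_m = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      j <- which(eligible)[which.min(d[eligible])]
      data.frame(station_id = pheno$station_id[i],
                 met_id = met$station_id[j],
                 dist_km = d[j], alt_diff_m = dz[j],
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
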