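# Synthetic Central-European station climates and mechanism-driven phenology
# records. Daily mean temperature is a sinusoidal seasonal cycle plus a
# station climate offset (altitude lapse, latitude gradient, microclimate),
# a secular warming ramp and AR(1) noise; onset dates are produced by the
# CA-HR process model itself plus observation noise, so the generator and
# the analysis chain share one mechanism.

#' Define a synthetic climate scenario
#'
#' Station structure: each of `n_locations` stations draws a latitude
#' (uniform 46--54 degrees N), longitude (6--16 degrees E) and altitude
#' (gamma-distributed, mean about 350 m, capped at 1600 m). Its climate
#' offset from the `annual_mean` reference (a sea-level, 48-degrees-N
#' reference value) is `-lapse_rate * alt/1000 - lat_gradient * (lat - 48)`
#' plus a microclimate term `N(0, microclimate_sd)`. This reproduces the
#' cold tail of real Central-European station networks, which is what makes
#' pooled CA-HR analysis informative about chilling-model structure.
#'
#' Daily mean temperature is
#' `annual_mean + offset - seasonal_amplitude * cos(2 pi (doy - coldest_day)/365.25)`
#' plus the warming offset and stationary AR(1) noise with marginal standard
#' deviation `noise_sd` and lag-1 autocorrelation `ar1_phi`. Maximum and
#' minimum temperatures are `t_mean +/- diurnal_half_range`. Warming is
#' `warming_rate * (year - years[1])`, capped after `warming_plateau_year`
#' if given, and applied uniformly over the year unless `winter_factor != 1`
#' (which scales the offset during November--February).
#'
#' @param n_locations Number of stations.
#' @param years Event years to support; the daily series starts 1 January of
#'   `years[1] - 1` so that each event year's dormancy season is covered.
#' @param annual_mean Reference annual mean temperature (degrees C).
#' @param seasonal_amplitude Half peak-to-trough seasonal range (degrees C).
#' @param coldest_day Day-of-year of the coldest climatological day.
#' @param ar1_phi Lag-1 autocorrelation of daily noise, in `[0, 1)`.
#' @param noise_sd Marginal standard deviation of the AR(1) noise (degrees C).
#' @param warming_rate Secular trend (degrees C per year).
#' @param warming_plateau_year Year after which the warming offset stays
#'   constant (`NULL` = no plateau).
#' @param diurnal_half_range Half the diurnal range (degrees C).
#' @param lapse_rate Altitude lapse rate (degrees C per km).
#' @param lat_gradient Latitude gradient (degrees C per degree N).
#' @param microclimate_sd Station microclimate spread (degrees C).
#' @param winter_factor Multiplier on the warming offset during Nov--Feb.
#' @param seed Integer seed; the scenario is fully reproducible.
#' @return A `climate_scenario` list.
#' @export
climate_scenario <- function(n_locations, years, annual_mean = 9,
                             seasonal_amplitude = 9, coldest_day = 15,
                             ar1_phi = 0.7, noise_sd = 3,
                             warming_rate = 0.025,
                             warming_plateau_year = NULL,
                             diurnal_half_range = 5,
                             lapse_rate = 6.5, lat_gradient = 0.35,
                             microclimate_sd = 1.5,
                             winter_factor = 1, seed = 42) {
  stopifnot(n_locations >= 1, length(years) >= 1,
            ar1_phi >= 0, ar1_phi < 1, noise_sd >= 0,
            seasonal_amplitude >= 0, diurnal_half_range >= 0)
  structure(
    list(n_locations = as.integer(n_locations), years = as.integer(years),
         annual_mean = annual_mean, seasonal_amplitude = seasonal_amplitude,
         coldest_day = coldest_day, ar1_phi = ar1_phi, noise_sd = noise_sd,
         warming_rate = warming_rate,
         warming_plateau_year = warming_plateau_year,
         diurnal_half_range = diurnal_half_range, lapse_rate = lapse_rate,
         lat_gradient = lat_gradient, microclimate_sd = microclimate_sd,
         winter_factor = winter_factor, seed = as.integer(seed)),
    class = "climate_scenario"
  )
}

#' Named scenario presets
#'
#' * `central_europe_historical`: 200 stations, event years 1951--2018,
#'   warming 0.025 degrees C/year (0.25 degrees C/decade, the observed
#'   Central-European winter rate over that period).
#' * `rcp45_like`: 30 stations, 2010--2099, 0.04 degrees C/year flattening
#'   after 2060 (about +2 degrees C by the 2090s relative to the 2010s).
#' * `rcp85_like`: 30 stations, 2010--2099, 0.053 degrees C/year with no
#'   plateau (about +4.5 degrees C by the 2090s).
#'
#' @param name Preset name.
#' @return A `climate_scenario` with documented constants and a fixed seed;
#'   calling twice gives an identical object.
#' @export
scenario_preset <- function(name = c("central_europe_historical",
                                     "rcp45_like", "rcp85_like")) {
  name <- match.arg(name)
  switch(name,
    central_europe_historical = climate_scenario(
      n_locations = 200, years = 1951:2018, warming_rate = 0.025, seed = 42
    ),
    rcp45_like = climate_scenario(
      n_locations = 30, years = 2010:2099, warming_rate = 0.04,
      warming_plateau_year = 2060, seed = 43
    ),
    rcp85_like = climate_scenario(
      n_locations = 30, years = 2010:2099, warming_rate = 0.053, seed = 44
    )
  )
}

#' Generate daily temperature series for a scenario
#'
#' @param scenario A [climate_scenario()].
#' @return A named list of [daily_series()], one per station
#'   (ids `"S001"`, `"S002"`, ...), each spanning 1 January of
#'   `years[1] - 1` through 31 December of the last year.
#' @export
generate_temperature <- function(scenario) {
  stopifnot(inherits(scenario, "climate_scenario"))
  sc <- scenario
  dates <- seq(as.Date(sprintf("%d-01-01", min(sc$years) - 1L)),
               as.Date(sprintf("%d-12-31", max(sc$years))), by = "day")
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1
  yr <- lt$year + 1900
  mon <- lt$mon + 1
  seasonal <- -sc$seasonal_amplitude *
    cos(2 * pi * (doy - sc$coldest_day) / 365.25)
  eff_year <- pmax(yr, min(sc$years))
  if (!is.null(sc$warming_plateau_year)) {
    eff_year <- pmin(eff_year, sc$warming_plateau_year)
  }
  warm <- sc$warming_rate * (eff_year - min(sc$years))
  if (sc$winter_factor != 1) {
    warm <- warm * ifelse(mon %in% c(11, 12, 1, 2), sc$winter_factor, 1)
  }
  base <- sc$annual_mean + seasonal + warm
  n <- length(dates)
  innov_sd <- sc$noise_sd * sqrt(1 - sc$ar1_phi^2)
  withr::with_seed(sc$seed, {
    ids <- sprintf("S%03d", seq_len(sc$n_locations))
    lat <- stats::runif(sc$n_locations, 46, 54)
    lon <- stats::runif(sc$n_locations, 6, 16)
    alt <- pmin(stats::rgamma(sc$n_locations, shape = 2, scale = 175), 1600)
    offset <- -sc$lapse_rate * alt / 1000 -
      sc$lat_gradient * (lat - 48) +
      stats::rnorm(sc$n_locations, 0, sc$microclimate_sd)
    out <- vector("list", sc$n_locations)
    names(out) <- ids
    for (i in seq_len(sc$n_locations)) {
      noise <- if (sc$noise_sd > 0) {
        as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                 sc$ar1_phi, method = "recursive"))
      } else {
        numeric(n)
      }
      tm <- base + offset[i] + noise
      out[[i]] <- daily_series(
        dates, tm,
        t_max = tm + sc$diurnal_half_range,
        t_min = tm - sc$diurnal_half_range,
        location_id = ids[i], lat = lat[i], lon = lon[i], alt = alt[i]
      )
    }
    out
  })
}

#' Station metadata table of a generated series set
#'
#' @param series_list Named list of [daily_series()].
#' @return Data frame with `station_id`, `lat`, `lon`, `alt`.
#' @export
station_table <- function(series_list) {
  data.frame(
    station_id = vapply(series_list, attr, "", "location_id"),
    lat = vapply(series_list, attr, 0, "lat"),
    lon = vapply(series_list, attr, 0, "lon"),
    alt = vapply(series_list, attr, 0, "alt"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Define a phenology-generating mechanism
#'
#' The mechanism is the CA-HR process model itself: onset in each season is
#' the first day whose heat accumulation (forcing model, from 1 January)
#' strictly exceeds `max(a_true + b_true * CA, 0)` with CA from the chilling
#' model (from 1 November). Observed onset adds rounded Gaussian day noise.
#' Defaults (`a_true = 600`, `b_true = -2` forcing units per chill unit,
#' 2-day observation noise) put onsets in mid spring under the default
#' climate, comparable to birch leaf-out.
#'
#' @param chilling_model,forcing_model Model ids of the true mechanism.
#' @param a_true,b_true HR(CA) rule coefficients; `b_true <= 0` for a
#'   valid-mechanism scenario.
#' @param obs_noise_sd Observation noise (days).
#' @param species,bbch Labels stamped on the generated records.
#' @param seed Integer seed for the observation noise.
#' @return A `mechanism_spec` list.
#' @export
mechanism_spec <- function(chilling_model = "C1", forcing_model = "F1",
                           a_true = 600, b_true = -2, obs_noise_sd = 2,
                           species = "synthetic_betula", bbch = 11,
                           seed = 1) {
  stopifnot(is.finite(a_true), is.finite(b_true), obs_noise_sd >= 0)
  structure(
    list(chilling_model = chilling_model, forcing_model = forcing_model,
         a_true = a_true, b_true = b_true, obs_noise_sd = obs_noise_sd,
         species = species, bbch = as.integer(bbch), seed = as.integer(seed)),
    class = "mechanism_spec"
  )
}

#' Generate phenology records from a mechanism
#'
#' Simulates the onset series of every station with the mechanism's process
#' model, adds rounded `N(0, obs_noise_sd)` day noise, and returns records in
#' the standard phenology layout. Seasons in which the heat requirement is
#' never met are dropped; their count is reported in the `n_dropped`
#' attribute.
#'
#' @param series_list Named list of [daily_series()].
#' @param mech A [mechanism_spec()].
#' @return Data frame with `station_id`, `species`, `bbch`, `year`, `doy`
#'   and attribute `n_dropped`.
#' @export
generate_phenology <- function(series_list, mech) {
  stopifnot(inherits(mech, "mechanism_spec"))
  params <- pheno_model_params(mech$a_true, mech$b_true,
                               mech$chilling_model, mech$forcing_model)
  withr::with_seed(mech$seed, {
    rows <- lapply(series_list, function(ser) {
      sim <- simulate_series(params, ser)
      if (mech$obs_noise_sd > 0) {
        jit <- round(stats::rnorm(nrow(sim), 0, mech$obs_noise_sd))
        sim$onset_doy <- sim$onset_doy + as.integer(jit)
      }
      sim
    })
    out <- do.call(rbind, rows)
    dropped <- sum(is.na(out$onset_doy))
    out <- out[!is.na(out$onset_doy), , drop = FALSE]
    out$onset_doy <- pmin(pmax(out$onset_doy, 1L), 366L)
    res <- data.frame(
      station_id = out$location_id,
      species = mech$species,
      bbch = mech$bbch,
      year = out$year,
      doy = out$onset_doy,
      row.names = NULL,
      stringsAsFactors = FALSE
    )
    attr(res, "n_dropped") <- dropped
    res
  })
}
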