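# Shared fixture builders. Everything is generated in code; no stored data.

# constant-temperature series spanning one dormancy season (or any range)
const_series <- function(t_mean, from = "2000-11-01", to = "2001-07-31",
                         diurnal = 5, location_id = "const") {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  tm <- rep(t_mean, length(dates))
  daily_series(dates, tm, t_max = tm + diurnal, t_min = tm - diurnal,
               location_id = location_id)
}

# seasonal sinusoid series with optional AR(1) noise, one or more years
sinus_series <- function(years, annual_mean = 9, amplitude = 9,
                         coldest = 15, noise_sd = 0, phi = 0,
                         seed = 1, location_id = "sin", offset = 0) {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years) - 1)),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  mu <- annual_mean + offset - amplitude * cos(2 * pi * (doy - coldest) / 365.25)
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, {
      as.numeric(stats::filter(rnorm(length(dates),
                                     0, noise_sd * sqrt(1 - phi^2)),
                               phi, method = "recursive"))
    })
  } else {
    0
  }
  tm <- mu + noise
  daily_series(dates, tm, t_max = tm + 5, t_min = tm - 5,
               location_id = location_id)
}

# one phenological record row
pheno_record <- function(station_id = "S1", species = "sp", bbch = 11,
                         year = 2001, doy = 100) {
  data.frame(station_id = station_id, species = species, bbch = bbch,
             year = year, doy = doy, stringsAsFactors = FALSE)
}

# a small valid-mechanism synthetic data set used by several test files
small_mechanism_data <- function(n_loc = 20, years = 1989:2018, seed = 7) {
  sc <- climate_scenario(n_locations = n_loc, years = years,
                         warming_rate = 0.04, seed = seed)
  series <- generate_temperature(sc)
  records <- generate_phenology(series, mechanism_spec(seed = seed + 1))
  list(scenario = sc, series = series, records = records)
}
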