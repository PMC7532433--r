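# End-to-end orchestration: synthetic data -> CA/HR -> trends -> validity ->
# process-model fits -> projections, with tidy CSV outputs. The command-line
# entry point (inst/cli/phenochill.R) is a thin wrapper over these functions.

# Tiny polynomial rolling hash for config stamping (no external digest
# dependency); arithmetic stays below 2^53 so doubles are exact.
.config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

.write_output <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param scenario A [climate_scenario()] or preset name.
#' @param mechanism A [mechanism_spec()].
#' @param chilling_ids,forcing_ids Models to analyse.
#' @param alpha Significance level.
#' @param min_years Station-level record threshold.
#' @param out_dir Output directory.
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(scenario = scenario_preset("central_europe_historical"),
                            mechanism = mechanism_spec(),
                            chilling_ids = .chilling_ids,
                            forcing_ids = "F1",
                            alpha = 0.05, min_years = 15,
                            out_dir = "phenochill_run") {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  list(scenario = scenario, mechanism = mechanism,
       chilling_ids = chilling_ids, forcing_ids = forcing_ids,
       alpha = alpha, min_years = min_years, out_dir = out_dir)
}

#' Run the full analysis chain on synthetic data
#'
#' Generates station climates and phenology records, computes per-record CA
#' and HR, per-station CA trends over the fixed 1 November--30 April window,
#' pooled validity verdicts, station-level fractions and process-model fits
#' for every chilling model, and writes each stage as a CSV stamped with the
#' configuration hash.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all stage results (`records`, `cahr`,
#'   `trends`, `validity`, `station_fractions`, `fits`, `config_hash`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  hash <- .config_hash(config[setdiff(names(config), "out_dir")])
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("generating temperatures (", config$scenario$n_locations,
      " stations, ", length(config$scenario$years), " years)")
  series <- generate_temperature(config$scenario)
  say("generating phenology records")
  records <- generate_phenology(series, config$mechanism)
  .write_output(records, file.path(config$out_dir, "records.csv"), hash)

  say("computing CA/HR per record")
  cahr <- cahr_table(records, series, config$chilling_ids,
                     config$forcing_ids)
  .write_output(cahr, file.path(config$out_dir, "cahr.csv"), hash)

  say("per-station CA trends (1 Nov - 30 Apr)")
  ca_yearly <- fixed_window_ca(series, config$chilling_ids,
                               config$scenario$years)
  trends <- trend_table(ca_yearly, config$alpha)
  .write_output(trends, file.path(config$out_dir, "trends.csv"), hash)

  say("validity classification")
  validity <- validity_table(cahr, config$chilling_ids, config$forcing_ids,
                             config$alpha)
  .write_output(validity, file.path(config$out_dir, "validity.csv"), hash)

  fr <- lapply(config$chilling_ids, function(cid) {
    f <- station_level_fraction(cahr, cid, config$forcing_ids[1],
                                config$min_years, config$alpha)
    data.frame(chilling_model = cid, fraction = f$fraction,
               n_stations = f$n_stations, stringsAsFactors = FALSE)
  })
  fr <- do.call(rbind, fr)
  .write_output(fr, file.path(config$out_dir, "station_fractions.csv"), hash)

  say("process-model fits")
  fits <- lapply(config$chilling_ids, function(cid) {
    f <- fit_pheno_model(cahr, cid, config$forcing_ids[1])
    data.frame(chilling_model = cid, a = f$a, b = f$b,
               b_lo = f$ci95_b[1], b_hi = f$ci95_b[2],
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, fits)
  .write_output(fits, file.path(config$out_dir, "fits.csv"), hash)

  writeLines(
    c(sprintf("config_hash: %s", hash),
      sprintf("n_records: %d", nrow(records)),
      sprintf("n_stations: %d", config$scenario$n_locations)),
    file.path(config$out_dir, "run_info.txt")
  )
  invisible(list(records = records, cahr = cahr, trends = trends,
                 validity = validity, station_fractions = fr, fits = fits,
                 series = series, config_hash = hash))
}

#' Yearly CA over the fixed 1 November--30 April window
#'
#' @param series_list Named list of [daily_series()].
#' @param chilling_ids Chilling models to accumulate.
#' @param years Event years.
#' @return Data frame `station_id`, `year`, `ca_<id>` columns.
#' @export
fixed_window_ca <- function(series_list, chilling_ids = .chilling_ids,
                            years) {
  rows <- list()
  for (ser in series_list) {
    st <- attr(ser, "location_id")
    for (y in years) {
      w <- season_window("nov1_prev_year", "apr30", y)
      row <- data.frame(station_id = st, year = as.integer(y),
                        stringsAsFactors = FALSE)
      for (cid in chilling_ids) {
        row[[paste0("ca_", cid)]] <- accumulate(ser, cid, w)$value
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Project onset series for fitted models under a scenario
#'
#' Simulates yearly onsets for each fitted chilling model under a (typically
#' future) climate scenario and summarizes the per-year mean and standard
#' deviation across stations.
#'
#' @param fits Data frame with columns `chilling_model`, `a`, `b` (as
#'   produced by [run_pipeline()]), or a list of `pheno_model_params`.
#' @param scenario A [climate_scenario()] for the projection period.
#' @param forcing_model Forcing model id used for simulation.
#' @return Data frame: `chilling_model`, `year`, `mean_doy`, `sd_doy`,
#'   `n_locations`.
#' @export
project_onsets <- function(fits, scenario, forcing_model = "F1") {
  series <- generate_temperature(scenario)
  if (is.data.frame(fits)) {
    fits <- lapply(seq_len(nrow(fits)), function(i) {
      pheno_model_params(fits$a[i], fits$b[i], fits$chilling_model[i],
                         forcing_model)
    })
  }
  out <- list()
  for (params in fits) {
    sims <- do.call(rbind, lapply(series, function(ser) {
      simulate_series(params, ser)
    }))
    agg_m <- stats::aggregate(onset_doy ~ year, sims, mean, na.action = stats::na.omit)
    agg_s <- stats::aggregate(onset_doy ~ year, sims, stats::sd)
    agg_n <- stats::aggregate(onset_doy ~ year, sims, length)
    out[[length(out) + 1]] <- data.frame(
      chilling_model = params$chilling_model,
      year = agg_m$year, mean_doy = agg_m$onset_doy,
      sd_doy = agg_s$onset_doy, n_locations = agg_n$onset_doy,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
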