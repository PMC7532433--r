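# CA-HR process model: onset prediction, simulation, evaluation metrics.

test_that("onset is the first day heat strictly exceeds the requirement", {
  ser10 <- const_series(10)
  p <- pheno_model_params(a = 100, b = 0)
  # day 10 reaches exactly 100 (not larger); day 11 is the onset
  expect_equal(predict_onset(p, ser10, 2001), 11L)
  ser0 <- const_series(0)
  expect_true(is.na(predict_onset(p, ser0, 2001)))
  expect_error(predict_onset(p, const_series(10, from = "2001-01-01"), 2001),
               "does not cover")
})

test_that("prediction equals an independent brute-force day loop", {
  brute_onset <- function(params, series, year) {
    start <- as.Date(sprintf("%d-11-01", year - 1))
    jan1 <- as.Date(sprintf("%d-01-01", year))
    end <- as.Date(sprintf("%d-07-31", year))
    days <- seq(jan1, end, by = "day")
    for (d in as.list(days)) {
      chill_days <- seq(start, d, by = "day")
      ca <- if (params$chilling_model == "C9") {
        tail(dynamic_chill_portions(
          series$t_mean[series$date %in% chill_days]), 1)
      } else {
        sum(chilling_rate(params$chilling_model,
                          series$t_mean[series$date %in% chill_days]))
      }
      force_days <- seq(jan1, d, by = "day")
      sel <- series$date %in% force_days
      heat <- sum(forcing_rate(params$forcing_model, series$t_mean[sel],
                               series$t_max[sel], series$t_min[sel]))
      if (heat > max(params$a + params$b * ca, 0)) {
        return(as.integer(d - jan1) + 1L)
      }
    }
    NA_integer_
  }
  # cold winter then warm spring, chilling-dependent threshold
  dates <- seq(as.Date("2000-11-01"), as.Date("2001-07-31"), by = "day")
  tm <- ifelse(dates < as.Date("2001-03-01"), 3, 10)
  ser <- daily_series(dates, tm, t_max = tm + 5, t_min = tm - 5)
  p <- pheno_model_params(a = 300, b = -1)
  expect_identical(predict_onset(p, ser, 2001), brute_onset(p, ser, 2001))
  withr::with_seed(77, {
    for (k in 1:8) {
      sern <- sinus_series(2001, noise_sd = 3, phi = 0.6, seed = 100 + k,
                           offset = runif(1, -4, 2))
      pk <- pheno_model_params(a = runif(1, 200, 700),
                               b = runif(1, -3, 0.5),
                               chilling_model = sample(paste0("C", 1:12), 1),
                               forcing_model = sample(paste0("F", 1:8), 1))
      expect_identical(predict_onset(pk, sern, 2001),
                       brute_onset(pk, sern, 2001),
                       info = paste(pk$chilling_model, pk$forcing_model, k))
    }
  })
})

test_that("stationary climate gives identical onsets; warming never delays", {
  ser <- sinus_series(2001:2003)   # no noise, no trend
  p <- pheno_model_params(a = 300, b = 0)
  sim <- simulate_series(p, ser)
  expect_equal(nrow(sim), 3)
  expect_true(all(sim$onset_doy == sim$onset_doy[1]))
  # +2 degrees after 1 Jan advances (or preserves) onset in every year
  warm <- ser
  jan_on <- format(warm$date, "%m") %in% sprintf("%02d", 1:7)
  warm$t_mean[jan_on] <- warm$t_mean[jan_on] + 2
  warm$t_max[jan_on] <- warm$t_max[jan_on] + 2
  warm$t_min[jan_on] <- warm$t_min[jan_on] + 2
  sim_w <- simulate_series(p, warm)
  expect_true(all(sim_w$onset_doy <= sim$onset_doy))
  # determinism: identical inputs give identical series
  expect_identical(sim, simulate_series(p, ser))
})

test_that("fitting records from a known mechanism recovers its parameters", {
  dat <- small_mechanism_data(n_loc = 20, years = 1989:2018, seed = 7)
  cahr <- cahr_table(dat$records, dat$series, chilling_ids = "C1")
  fit <- fit_pheno_model(cahr, "C1", "F1")
  expect_equal(fit$b, -2, tolerance = 0.2 * 2)     # within 20 percent
  expect_equal(fit$a, 600, tolerance = 0.1 * 600)  # within 10 percent
  expect_lt(fit$ci95_b[2], 0)   # slope confidently negative
})

test_that("spatial and trend evaluation metrics are exact on known vectors", {
  ev <- evaluate_spatial(c(100, 110, 120), c(100, 110, 120))
  expect_equal(ev$r2, 1)
  expect_equal(ev$rmse, 0)
  ev2 <- evaluate_spatial(c(100, 110, 120), c(103, 113, 123))
  expect_equal(ev2$r2, 1)
  expect_equal(ev2$rmse, 3)
  ev3 <- evaluate_spatial(c(100, 110, 120), c(102, 108, 123))
  expect_equal(ev3$rmse, sqrt((4 + 4 + 9) / 3), tolerance = 1e-9)
  tr <- evaluate_trends(c(-0.2, -0.3, -0.1), c(-0.2, -0.3, -0.1) - 0.05)
  expect_equal(tr$rmse, 0.05, tolerance = 1e-12)
  expect_error(evaluate_spatial(1:3, 1:4), "mismatch")
})

test_that("moving average is centered, edge-truncated and linearity-preserving", {
  expect_equal(moving_average(rep(7, 20)), rep(7, 20))
  lin <- as.numeric(1:30)
  sm <- moving_average(lin)
  expect_equal(sm[6:25], lin[6:25])   # interior points unchanged
  spike <- c(rep(0, 5), 11, rep(0, 5))
  expect_equal(moving_average(spike)[6], 1)
  expect_error(moving_average(1:10, window = 4), "window")
})

test_that("decadal advance follows the sign convention", {
  ons <- data.frame(year = c(2010:2018, 2090:2099),
                    onset_doy = c(rep(100, 9), rep(85, 10)))
  expect_equal(decadal_advance(ons), 15)
  ons$onset_doy <- 100
  expect_equal(decadal_advance(ons), 0)
  ons$onset_doy[ons$year >= 2090] <- 110
  expect_equal(decadal_advance(ons), -10)
  expect_error(decadal_advance(ons[ons$year < 2050, ]), "decades")
})
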