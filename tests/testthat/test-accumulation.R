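# Calendar windows and CA/HR accumulation.

test_that("windows resolve to the correct closed date ranges", {
  w <- resolve_window(season_window("nov1_prev_year", "apr30", 2001))
  expect_equal(w$n_days, 181)           # 30+31+31+28+31+30, no leap day
  expect_equal(w$start, as.Date("2000-11-01"))
  expect_equal(w$end, as.Date("2001-04-30"))
  expect_equal(resolve_window(season_window("nov1_prev_year", "apr30",
                                            2000))$n_days, 182)  # leap year
  expect_equal(resolve_window(season_window("jan1", "onset_date", 2001,
                                            onset_doy = 1))$n_days, 1)
  expect_error(
    resolve_window(season_window("feb1", "onset_date", 2001, onset_doy = 5)),
    "empty window"
  )
})

test_that("accumulation sums daily rates over the window", {
  ser3 <- const_series(3)
  w <- season_window("nov1_prev_year", "apr30", 2001)
  expect_equal(accumulate(ser3, "C1", w)$value, 181)
  ser20 <- const_series(20)
  w10 <- season_window("jan1", "onset_date", 2001, onset_doy = 10)
  expect_equal(accumulate(ser20, "C7", w10)$value, -10)
  ser10 <- const_series(10)
  w31 <- season_window("jan1", "onset_date", 2001, onset_doy = 31)
  expect_equal(accumulate(ser10, "F1", w31)$value, 310)
  # C9 over a window equals the fresh-state portion total
  expect_equal(accumulate(ser3, "C9", w)$value,
               tail(dynamic_chill_portions(rep(3, 181)), 1))
})

test_that("missing days are rejected by default and tolerated on request", {
  ser <- const_series(3)
  ser$t_mean[50] <- NA
  w <- season_window("nov1_prev_year", "apr30", 2001)
  expect_error(accumulate(ser, "C1", w), "missing")
  res <- accumulate(ser, "C1", w, na_tol = 0.05)
  expect_equal(res$value, 180)   # the missing day contributes rate 0
  expect_equal(res$n_missing, 1)
  ser$t_mean[51:70] <- NA
  expect_error(accumulate(ser, "C1", w, na_tol = 0.05), "missing")
})

test_that("per-record CA/HR windows follow the calendar", {
  rec <- pheno_record(doy = 100)
  ser3 <- const_series(3)
  out <- ca_hr_for_record(rec, ser3, chilling_ids = "C1",
                          forcing_ids = "F1")
  # 61 days Nov-Dec 2000 plus DOY 100 days of 2001, rate 1 throughout
  expect_equal(out$ca_C1, 161)
  ser10 <- const_series(10)
  out10 <- ca_hr_for_record(rec, ser10, chilling_ids = "C1",
                            forcing_ids = "F1")
  expect_equal(out10$hr_F1, 1000)
  feb <- ca_hr_for_record(rec, ser10, chilling_ids = "C1",
                          forcing_ids = "F1", hr_start = "feb1")
  expect_equal(out10$hr_F1 - feb$hr_F1, 310)  # 31 January days at rate 10
})

test_that("lengthening the window never decreases CA except for C7", {
  ser <- sinus_series(2001, noise_sd = 3, phi = 0.5, seed = 3)
  for (id in paste0("C", c(1:6, 8:12))) {
    v1 <- accumulate(ser, id,
                     season_window("nov1_prev_year", "onset_date", 2001,
                                   onset_doy = 100))$value
    v2 <- accumulate(ser, id,
                     season_window("nov1_prev_year", "onset_date", 2001,
                                   onset_doy = 130))$value
    expect_gte(v2, v1)
  }
})

test_that("uniform warming shifts F1 heat sums by exactly n_days * delta", {
  ser <- const_series(10)
  w <- season_window("jan1", "onset_date", 2001, onset_doy = 90)
  base <- accumulate(ser, "F1", w)$value
  ser_up <- const_series(10 + 1.5)
  expect_equal(accumulate(ser_up, "F1", w)$value, base + 90 * 1.5,
               tolerance = 1e-9)
})

test_that("accumulation matches a naive per-day loop on random series", {
  naive_accumulate <- function(series, model_id, window) {
    rw <- resolve_window(window)
    days <- seq(rw$start, rw$end, by = "day")
    if (model_id == "C9") {
      st <- dynamic_chill_state()
      for (d in as.list(days)) {
        t <- series$t_mean[series$date == d]
        st <- dynamic_chill_step(st, t)$state
      }
      return(st$portions)
    }
    tot <- 0
    for (d in as.list(days)) {
      i <- which(series$date == d)
      tot <- tot + if (startsWith(model_id, "C")) {
        chilling_rate(model_id, series$t_mean[i])
      } else {
        forcing_rate(model_id, series$t_mean[i], series$t_max[i],
                     series$t_min[i])
      }
    }
    tot
  }
  withr::with_seed(42, {
    ids <- c(paste0("C", 1:12), paste0("F", 1:8))
    for (k in 1:100) {
      ser <- sinus_series(2001, noise_sd = runif(1, 0, 4),
                          phi = runif(1, 0, 0.9), seed = k,
                          offset = runif(1, -4, 4))
      id <- sample(ids, 1)
      w <- season_window("nov1_prev_year", "onset_date", 2001,
                         onset_doy = sample(60:150, 1))
      expect_equal(accumulate(ser, id, w)$value,
                   naive_accumulate(ser, id, w), tolerance = 1e-9,
                   info = paste(id, k))
    }
  })
})

test_that("cahr_table equals ca_hr_for_record looped over rows", {
  dat <- small_mechanism_data(n_loc = 3, years = 2008:2012)
  recs <- dat$records
  tab <- cahr_table(recs, dat$series, chilling_ids = c("C1", "C7", "C9"),
                    forcing_ids = c("F1", "F5"))
  for (i in seq_len(nrow(recs))) {
    one <- ca_hr_for_record(recs[i, ], dat$series[[recs$station_id[i]]],
                            chilling_ids = c("C1", "C7", "C9"),
                            forcing_ids = c("F1", "F5"))
    expect_equal(tab$ca_C1[i], one$ca_C1, tolerance = 1e-9)
    expect_equal(tab$ca_C7[i], one$ca_C7, tolerance = 1e-9)
    expect_equal(tab$ca_C9[i], one$ca_C9, tolerance = 1e-9)
    expect_equal(tab$hr_F1[i], one$hr_F1, tolerance = 1e-9)
    expect_equal(tab$hr_F5[i], one$hr_F5, tolerance = 1e-9)
  }
})
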