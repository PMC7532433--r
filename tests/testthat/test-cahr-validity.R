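# CA-HR validity classification, binning and regression.

make_cahr <- function(ca, hr, station_id = "S1", year = NULL) {
  n <- length(ca)
  data.frame(station_id = rep(station_id, length.out = n),
             species = "sp", bbch = 11,
             year = if (is.null(year)) seq_len(n) + 2000 else year,
             doy = 100, ca_C1 = ca, hr_F1 = hr,
             stringsAsFactors = FALSE)
}

test_that("pearson_test matches hand-computed correlations", {
  expect_equal(pearson_test(1:10, 2 * (1:10))$r, 1, tolerance = 1e-12)
  expect_equal(pearson_test(1:10, -(1:10) + 7)$r, -1, tolerance = 1e-12)
  pt <- pearson_test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(pt$r, 0.6, tolerance = 1e-12)
  expect_equal(pt$n, 4)
  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_test(1:2, 2:1), "n >= 3")
})

test_that("validity verdict requires a significantly negative correlation", {
  withr::with_seed(21, {
    ca <- runif(300, 50, 250)
    hr_neg <- 600 - 0.5 * ca + rnorm(300, 0, 5)
    hr_indep <- rnorm(1000, 300, 30)
  })
  v <- classify_model_validity(make_cahr(ca, hr_neg), "C1")
  expect_equal(v$verdict, "valid")
  expect_lt(v$r, 0)
  v2 <- classify_model_validity(
    make_cahr(runif(1000, 50, 250), hr_indep), "C1")
  expect_equal(v2$verdict, "invalid")
  # positive relation is invalid no matter how significant
  v3 <- classify_model_validity(make_cahr(ca, 100 + 2 * ca), "C1")
  expect_equal(v3$verdict, "invalid")
})

test_that("verdicts are invariant to record order and HR rescaling", {
  withr::with_seed(31, {
    ca <- runif(200, 50, 250)
    hr <- 500 - 1.5 * ca + rnorm(200, 0, 20)
  })
  rec <- make_cahr(ca, hr)
  v <- classify_model_validity(rec, "C1")
  perm <- rec[sample(nrow(rec)), ]
  vp <- classify_model_validity(perm, "C1")
  expect_equal(v$r, vp$r, tolerance = 1e-12)
  rec2 <- rec
  rec2$hr_F1 <- 3.8 * rec2$hr_F1 + 250   # affine change of forcing units
  va <- classify_model_validity(rec2, "C1")
  expect_equal(v$r, va$r, tolerance = 1e-10)
  expect_equal(v$p, va$p, tolerance = 1e-10)
  expect_equal(v$verdict, va$verdict)
})

test_that("station-level fractions respect the record-length filter", {
  withr::with_seed(41, {
    recs <- do.call(rbind, lapply(sprintf("S%02d", 1:6), function(s) {
      ca <- runif(20, 50, 250)
      make_cahr(ca, 700 - 2 * ca, station_id = s, year = 2000 + 1:20)
    }))
  })
  out <- station_level_fraction(recs, "C1", min_years = 15)
  expect_false(out$empty)
  expect_equal(out$n_stations, 6)
  expect_equal(out$fraction, 1)   # exact negative line at every station
  short <- recs[recs$year <= 2005, ]
  out2 <- station_level_fraction(short, "C1", min_years = 15)
  expect_true(out2$empty)
  expect_true(is.na(out2$fraction))
})

test_that("equal-count binning balances group sizes deterministically", {
  withr::with_seed(51, {
    rec40 <- make_cahr(runif(40, 0, 100), runif(40, 0, 100))
  })
  b40 <- bin_equal_count(rec40, "C1", k = 20)
  expect_equal(b40$n, rep(2L, 20))
  expect_equal(sum(b40$n), 40)
  withr::with_seed(52, {
    rec45 <- make_cahr(runif(45, 0, 100), runif(45, 0, 100))
  })
  b45 <- bin_equal_count(rec45, "C1", k = 20)
  expect_equal(b45$n, c(rep(3L, 5), rep(2L, 15)))  # extras at the low-CA end
  expect_true(all(diff(b45$ca_mean) > 0))           # groups ordered by CA
  # ties: identical CA everywhere still yields balanced, reproducible groups
  ties <- make_cahr(rep(10, 45), 1:45,
                    station_id = sprintf("S%02d", rep(1:9, each = 5)),
                    year = rep(2001:2005, 9))
  bt1 <- bin_equal_count(ties, "C1", k = 20)
  bt2 <- bin_equal_count(ties[sample(45), ], "C1", k = 20)
  expect_equal(bt1, bt2)
  expect_equal(bt1$n, c(rep(3L, 5), rep(2L, 15)))
  expect_error(bin_equal_count(rec40[1:10, ], "C1", k = 20), "n >= k")
})

test_that("CA-HR regression recovers exact and noisy lines", {
  ca <- seq(10, 200, length.out = 50)
  fit <- fit_ca_hr_regression(make_cahr(ca, 500 - 2 * ca))
  expect_equal(fit$a, 500, tolerance = 1e-9)
  expect_equal(fit$b, -2, tolerance = 1e-12)
  expect_lt(diff(fit$ci95_b), 1e-8)   # zero-width interval on an exact line
  expect_error(fit_ca_hr_regression(make_cahr(rep(5, 10), 1:10)),
               "degenerate")
  withr::with_seed(61, {
    can <- runif(500, 50, 250)
    fitn <- fit_ca_hr_regression(make_cahr(can, 500 - 2 * can +
                                             rnorm(500, 0, 20)))
  })
  expect_true(fitn$ci95_b[1] <= -2 && -2 <= fitn$ci95_b[2])
  expect_true(fitn$ci95_a[1] <= 500 && 500 <= fitn$ci95_a[2])
})

test_that("group comparison detects slope differences and not null ones", {
  withr::with_seed(71, {
    null_sig <- vapply(1:100, function(i) {
      ca <- runif(200, 50, 250)
      hr <- 500 - 2 * ca + rnorm(200, 0, 30)
      gc <- group_compare(make_cahr(ca, hr), rep(c(TRUE, FALSE), 100))
      gc$p_slope_diff < 0.05
    }, NA)
  })
  expect_gte(mean(!null_sig), 0.90)
  withr::with_seed(72, {
    ca <- runif(1000, 50, 250)
    split <- rep(c(TRUE, FALSE), 500)
    hr <- ifelse(split, 800 - 2 * ca, 1200 - 4 * ca) + rnorm(1000, 0, 20)
  })
  gc <- group_compare(make_cahr(ca, hr), split)
  expect_lt(gc$p_slope_diff, 0.001)
  expect_equal(gc$slope_diff, 2, tolerance = 0.2)
  expect_error(group_compare(make_cahr(ca, hr), rep(TRUE, 1000)),
               "nonempty")
})
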