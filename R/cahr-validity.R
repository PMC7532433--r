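# Validity testing of chilling models against the physiological expectation
# that more winter chilling lowers the spring heat requirement: a chilling
# model is valid when its CA is significantly negatively correlated with HR.

#' Pearson correlation with two-sided p-value
#'
#' Standard Pearson product-moment correlation; the two-sided p-value comes
#' from the t distribution with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return A list with `r`, `p` and `n`.
#' @examples
#' pearson_test(c(1, 2, 3, 4), c(2, 1, 4, 3))$r   # 0.6
#' @export
pearson_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Validity verdict for one chilling model
#'
#' Pools all records of one species (across stations and years) and tests the
#' Pearson correlation between the chilling model's CA and the forcing
#' model's HR. The model is `valid` iff r < 0 and p < alpha.
#'
#' @param records A CA-HR table as returned by [cahr_table()] (or any data
#'   frame with the needed `ca_`/`hr_` columns), already restricted to one
#'   species.
#' @param chilling_model,forcing_model Model ids naming the `ca_<id>` and
#'   `hr_<id>` columns to use.
#' @param alpha Significance level; default 0.05.
#' @return A `validity_verdict` list: `species`, `chilling_model`,
#'   `forcing_model`, `r`, `p`, `n`, `verdict` (`"valid"` or `"invalid"`).
#' @export
classify_model_validity <- function(records, chilling_model,
                                    forcing_model = "F1", alpha = 0.05) {
  ca <- records[[paste0("ca_", chilling_model)]]
  hr <- records[[paste0("hr_", forcing_model)]]
  if (is.null(ca) || is.null(hr)) {
    stop("records lack ca_", chilling_model, " or hr_", forcing_model,
         call. = FALSE)
  }
  pt <- pearson_test(ca, hr)
  structure(
    list(
      species = if ("species" %in% names(records))
        paste(unique(records$species), collapse = "+") else NA_character_,
      chilling_model = chilling_model, forcing_model = forcing_model,
      r = pt$r, p = pt$p, n = pt$n,
      verdict = if (pt$r < 0 && pt$p < alpha) "valid" else "invalid"
    ),
    class = "validity_verdict"
  )
}

#' Validity table over chilling x forcing model combinations
#'
#' @param records CA-HR table (one species) with the needed columns.
#' @param chilling_ids,forcing_ids Model ids to cross.
#' @param alpha Significance level.
#' @return Tidy data frame: `species`, `chilling_model`, `forcing_model`,
#'   `r`, `p`, `n`, `verdict`.
#' @export
validity_table <- function(records, chilling_ids = .chilling_ids,
                           forcing_ids = "F1", alpha = 0.05) {
  grid <- expand.grid(chilling_model = chilling_ids,
                      forcing_model = forcing_ids,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- classify_model_validity(records, grid$chilling_model[i],
                                 grid$forcing_model[i], alpha)
    data.frame(species = v$species, chilling_model = v$chilling_model,
               forcing_model = v$forcing_model, r = v$r, p = v$p, n = v$n,
               verdict = v$verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of long-record stations with a significantly negative CA-HR r
#'
#' Stations with at least `min_years` records are tested individually; the
#' result is the fraction of qualifying stations whose CA-HR Pearson r is
#' negative with p < alpha.
#'
#' @param records CA-HR table with `station_id`.
#' @param chilling_model,forcing_model Model ids.
#' @param min_years Minimum number of records per station; default 15.
#' @param alpha Significance level.
#' @return A list: `fraction` (NA if no station qualifies), `n_stations`,
#'   `stations` (data frame station_id, r, p, sig_neg), `empty` flag.
#' @export
station_level_fraction <- function(records, chilling_model,
                                   forcing_model = "F1", min_years = 15,
                                   alpha = 0.05) {
  ca_col <- paste0("ca_", chilling_model)
  hr_col <- paste0("hr_", forcing_model)
  per_st <- split(records, records$station_id)
  per_st <- per_st[vapply(per_st, nrow, 0L) >= min_years]
  if (!length(per_st)) {
    return(list(fraction = NA_real_, n_stations = 0L,
                stations = data.frame(), empty = TRUE))
  }
  rows <- lapply(per_st, function(d) {
    pt <- pearson_test(d[[ca_col]], d[[hr_col]])
    data.frame(station_id = d$station_id[1], r = pt$r, p = pt$p,
               sig_neg = pt$r < 0 && pt$p < alpha,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(fraction = mean(tab$sig_neg), n_stations = nrow(tab),
       stations = tab, empty = FALSE)
}

#' Equal-count binning of CA-HR records
#'
#' Orders records by CA (ties broken by station then year, so the grouping is
#' deterministic) and splits them into `k` groups of as equal size as
#' possible: the first `n %% k` groups, at the low-CA end, receive one extra
#' record. Used for presentation of the pooled CA-HR cloud; model fitting is
#' done on raw records.
#'
#' @param records CA-HR table.
#' @param chilling_model,forcing_model Model ids selecting the CA and HR
#'   columns.
#' @param k Number of groups; default 20. Requires `nrow(records) >= k`.
#' @return Data frame with one row per group: `group`, `n`, `ca_mean`,
#'   `ca_sd`, `hr_mean`, `hr_sd`.
#' @export
bin_equal_count <- function(records, chilling_model, forcing_model = "F1",
                            k = 20) {
  n <- nrow(records)
  stopifnot(n >= k, k >= 1)
  ca <- records[[paste0("ca_", chilling_model)]]
  hr <- records[[paste0("hr_", forcing_model)]]
  ord <- order(ca, records$station_id, records$year)
  ca <- ca[ord]; hr <- hr[ord]
  base <- n %/% k; extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  grp <- rep(seq_len(k), times = sizes)
  data.frame(
    group = seq_len(k),
    n = sizes,
    ca_mean = as.numeric(tapply(ca, grp, mean)),
    ca_sd = as.numeric(tapply(ca, grp, stats::sd)),
    hr_mean = as.numeric(tapply(hr, grp, mean)),
    hr_sd = as.numeric(tapply(hr, grp, stats::sd))
  )
}

#' Fit the linear CA-HR relationship
#'
#' Ordinary least-squares fit of HR on CA with Wald 95% confidence intervals
#' for intercept and slope. Accepts either a raw CA-HR table (used for the
#' process model) or the output of [bin_equal_count()] (columns `ca_mean`,
#' `hr_mean`; used for presentation fits).
#'
#' @param records CA-HR table or binned-group table.
#' @param chilling_model,forcing_model Model ids (ignored for binned input).
#' @return A list: `a` (intercept), `b` (slope), `ci95_a`, `ci95_b` (length-2
#'   vectors), `r2`, `n`.
#' @export
fit_ca_hr_regression <- function(records, chilling_model = "C1",
                                 forcing_model = "F1") {
  if (all(c("ca_mean", "hr_mean") %in% names(records))) {
    ca <- records$ca_mean; hr <- records$hr_mean
  } else {
    ca <- records[[paste0("ca_", chilling_model)]]
    hr <- records[[paste0("hr_", forcing_model)]]
  }
  ok <- is.finite(ca) & is.finite(hr)
  ca <- ca[ok]; hr <- hr[ok]
  if (length(ca) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(ca) == 0) {
    stop("degenerate design: CA has zero variance", call. = FALSE)
  }
  fit <- stats::lm(hr ~ ca)
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  list(
    a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
    ci95_a = unname(ci[1, ]), ci95_b = unname(ci[2, ]),
    r2 = suppressWarnings(summary(fit)$r.squared), n = length(ca)
  )
}

#' Compare CA-HR regressions between two record groups
#'
#' Splits the records by a logical predicate (e.g., latitude below 50.65
#' degrees N), fits the CA-HR regression in each group, and tests equality of
#' slopes via the interaction term of a pooled model.
#'
#' @param records CA-HR table.
#' @param split Logical vector, one element per record (`TRUE` = group A).
#' @param chilling_model,forcing_model Model ids.
#' @return A list: `fit_a`, `fit_b` (per-group fits as in
#'   [fit_ca_hr_regression()]), `slope_diff`, `p_slope_diff` (two-sided test
#'   of equal slopes), `n_a`, `n_b`.
#' @export
group_compare <- function(records, split, chilling_model = "C1",
                          forcing_model = "F1") {
  stopifnot(length(split) == nrow(records), is.logical(split))
  if (!any(split) || all(split)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  fit_a <- fit_ca_hr_regression(records[split, , drop = FALSE],
                                chilling_model, forcing_model)
  fit_b <- fit_ca_hr_regression(records[!split, , drop = FALSE],
                                chilling_model, forcing_model)
  ca <- records[[paste0("ca_", chilling_model)]]
  hr <- records[[paste0("hr_", forcing_model)]]
  g <- factor(ifelse(split, "a", "b"))
  pooled <- stats::lm(hr ~ ca * g)
  coefs <- summary(pooled)$coefficients
  int_row <- grep(":", rownames(coefs))
  list(
    fit_a = fit_a, fit_b = fit_b,
    slope_diff = fit_a$b - fit_b$b,
    p_slope_diff = coefs[int_row, 4],
    n_a = sum(split), n_b = sum(!split)
  )
}
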