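---
title: "Chilling models, the CA-HR relationship and onset simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chilling models, the CA-HR relationship and onset simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenochill)
```

## The scientific problem

Spring phenology of temperate perennials (budburst, leaf-out, flowering) is
controlled by two opposing thermal signals. Warm spring temperatures
(*forcing*) push buds toward growth; the amount of accumulated forcing a bud
needs — its heat requirement, HR — is not fixed, but depends on how much
cold the bud experienced during winter dormancy (*chilling*). Physiology and
decades of twig and sapling experiments agree on the direction of that
dependence: **more chilling accumulation (CA) lowers the heat requirement**.
A winter that delivers too little chilling leaves buds needing more spring
heat, which slows the phenological advance that spring warming would
otherwise produce.

The catch is that "chilling" is not directly observable. It is measured
through *chilling models* — daily (or hourly) rate functions that translate
temperature into chill effectiveness — and the many models in use disagree
about which temperatures count. Some treat every day below 5 or 7 °C as
equally effective, including frost days; others exclude freezing
temperatures entirely or weight a band around 2–9 °C. Under a warming
climate these choices diverge dramatically: models that count frost days see
chilling *decline* as winters warm, while models with a 0 °C floor see
frost days converted into effective days and chilling *increase*. A chilling
model whose CA is *positively* correlated with HR contradicts the
physiological expectation, and projections built on it misattribute the
chilling brake on spring advance.

This package implements the full model suite and the analysis chain that
classifies each chilling model as physiologically **valid** (CA
significantly negatively correlated with HR) or **invalid**, and propagates
the consequences into onset simulation under warming scenarios.

## The rate models

Twenty daily rate functions form a uniform registry (`list_models()`).

**Chilling models C1–C12** (input: daily mean temperature `T`, output in
chill units/day):

* C1–C6: unit-step threshold models. Rate 1 when `T ≤ 5` (C1), `−10 ≤ T ≤ 5`
  (C2), `0 ≤ T ≤ 5` (C3), `T ≤ 7` (C4), `−10 ≤ T ≤ 7` (C5), `0 ≤ T ≤ 7`
  (C6); 0 otherwise. Boundary inclusivity follows the printed inequalities
  verbatim (e.g. C1 gives rate 1 at exactly 5 °C).
* C7: the Utah model — weights 0, 0.5, 1, 0.5, 0, −0.5, −1 over bands with
  breakpoints 1.4, 2.4, 9.1, 12.4, 15.9 and 18 °C. The only model with
  negative rates (warm days cancel accumulated chill).
* C8: the Utah model with the negative weights replaced by 0.
* C9: the dynamic chill-portion model, the only *stateful* model. Cold
  builds a thermally labile precursor pool; when the pool completes one
  unit, a temperature-dependent fraction is banked irreversibly as a chill
  portion; warm spells destroy the unconverted pool but never banked
  portions. This implementation follows the standard two-step recursion of
  the horticultural literature with its published constant set (`a0 = 139500`, `a1 = 2.567e18`,
  `e0 = 4153.5`, `e1 = 12888.8`, `slp = 1.6`, `tetmlt = 277` K), applied at
  daily resolution because every model in the suite is applied daily.
* C10: a three-parameter Weibull-shaped rate
  `3.13 x^2.10 exp(−x^3.10)` with `x = (T + 4.66)/10.93`, overridden by a
  unit plateau on the open interval (2.5, 7.4) and by 0 outside
  [−4.7, 16] — implemented exactly as printed, accepting the small
  discontinuities at 2.5 and 7.4 °C. For `T` in [−4.7, −4.66) the printed
  expression has a negative base under a fractional exponent; the base is
  floored at zero there, which returns rate 0 and matches the limit from
  above.
* C11, C12: triangular rates. C11 rises from −3.4 °C to an optimum at 5 °C
  and falls to zero at 10.4 °C; C12 uses the optimum 0.2 °C and upper limit
  6.9 °C, with lower limit −6.5 °C.

**Forcing models F1–F8** (output in forcing units/day, always ≥ 0):

* F1 `max(T, 0)` and F2 `max(T − 5, 0)`: growing-degree-day rates of mean
  temperature. F1 is the reference forcing model throughout the analysis.
* F3 `max(Tmax, 0)`, F4 `max(Tmax − 5, 0)`: daytime (maximum-temperature)
  GDD variants.
* F5 `0.75 max(Tmax − 5, 0) + 0.25 max(Tmin − 5, 0)`: daytime-weighted
  (the daytime effect on leaf unfolding is roughly threefold the nighttime
  effect).
* F6: logistic rate `28.4 / (1 + exp(−0.185 (T − 18.5)))` for `T > 0`,
  else 0. F7: logistic `1 / (1 + exp(−0.47 T + 6.49))`.
* F8: growing-degree-hour (GDH) cosine response with cardinal temperatures
  `TL = 4`, `Tu = 25`, `Tc = 36` °C, applied at daily resolution with the
  stress factor omitted. The printed condition of the middle branch reads
  `TL ≥ T ≥ Tu`; it is implemented as `TL ≤ T ≤ Tu`, the only reading under
  which the three branches partition the temperature axis. The function is
  continuous on `[TL, Tc]` and zero outside.

```{r}
grid <- round(seq(-10, 15, 0.01), 2)
grid[which.max(chilling_rate("C12", grid))]   # triangular optimum, deg C
forcing_rate("F8", 25)                        # GDH maximum, units/day
```

## Accumulation windows

CA and HR are sums of daily rates over closed calendar windows
(`season_window()`, `accumulate()`):

* **CA**: 1 November of the previous year (the conventional onset of
  endodormancy) to either 30 April (fixed-window trend analysis) or the
  onset date (per-record CA–HR analysis). The dynamic model's state is
  reset at each 1 November; no carry-over between seasons.
* **HR**: 1 January to the onset date; 15 January and 1 February are
  supported as sensitivity alternatives.

Day-of-year is 1-based, windows are inclusive on both ends, and leap days
count as ordinary days. Missing days inside a window are an error by
default; an explicit tolerance (`na_tol`) admits up to that fraction of
missing days as rate 0. The choice is deliberately conservative — gridded
climate products such as E-OBS are serially complete and the generator
produces complete series, so silent gap tolerance would only mask bugs.

## Validity classification

For each chilling model, all records of a species are pooled across
stations and years and the Pearson correlation between per-record CA and HR
is tested (`classify_model_validity()`); the model is **valid** iff
`r < 0` with two-sided `p < 0.05` (the t-test with n − 2 degrees of
freedom). Supporting analyses round out the classification: per-station
verdicts restricted to stations with ≥ 15 record years
(`station_level_fraction()`), 20-group equal-count binning of the pooled
cloud for display (`bin_equal_count()`), per-station CA trends with a
four-way significance classification (`linear_trend()`, α = 0.05
uniformly for every test in the package), and a latitude-band slope
comparison via an interaction term (`group_compare()`).

Two small conventions are fixed and documented here:
equal-count binning assigns the `n mod k` extra records to the lowest-CA
groups with ties broken by (station, year); and a trend slope of exactly
zero classifies as insignificant-negative, never significant.

The process model is fitted on **raw records**, not binned means — the
prediction rule is defined over all records, and binning is presentation
only.

## The onset simulator

`predict_onset()` implements the daily rule: from 1 January, heat
accumulates under the forcing model while CA (from 1 November) keeps
updating the requirement `HR(CA) = max(a + b·CA, 0)`; onset is the **first
day whose heat accumulation is strictly larger** than the requirement —
exact equality does not trigger. The floor at zero exists because a
negative heat requirement is meaningless under positively-fitted (invalid)
rules; for valid fits it never binds. If the requirement is never exceeded
by 31 July the season returns a sentinel (`NA`), not an error — extreme
parameters can legitimately produce no onset. Chilling continues to
accumulate past 30 April up to the onset day itself, consistent with the
per-record CA definition. Fits are pooled per species over all stations;
`evaluate_spatial()` and `evaluate_trends()` compare simulated and observed
mean dates and per-location trends (R², RMSE), and `decadal_advance()`
summarizes projections as the mean onset of 2010–2018 minus that of
2090–2099 (positive = earlier; decade bounds configurable).

## The synthetic world

Everything above is exercised on synthetic data
(`climate_scenario()`, `generate_temperature()`, `generate_phenology()`),
built to carry the statistical structure the analysis relies on — no
external archives are needed.

**Daily temperature.** A sinusoidal seasonal cycle (reference annual mean
9 °C, amplitude 9 °C, coldest day 15 January) plus a station climate
offset, a secular warming ramp, and stationary AR(1) noise (marginal SD
3 °C, lag-1 autocorrelation 0.7 — values typical of Central-European daily
anomalies). Maximum/minimum temperatures sit ± 5 °C around the mean.

**Station structure.** Real phenological networks span lowlands to cold
uplands, and that between-station climate gradient is what makes *pooled*
CA–HR correlations informative: across stations, warm sites accumulate
both more heat by any given date and more chilling under models with a
0 °C floor, exposing the structural difference between model families.
Each synthetic station therefore draws an altitude (gamma, mean ≈ 350 m,
capped at 1600 m) and latitude (uniform 46–54° N), and its climate offset
is `−6.5 °C/km × alt − 0.35 °C/° × (lat − 48)` plus N(0, 1.5 °C)
microclimate. The resulting station winter means are ≈ −1 ± 2.3 °C. A
spatially uniform network (all stations at the reference climate) was
considered and rejected: without the cold tail, within-station weather
noise — which couples every overlapping temperature band positively —
dominates the pooled correlations and the boundary models (notably the
0–5 °C band model C3) fail to show their real-world positive CA–HR
association.

**Warming.** Linear at `warming_rate` (°C/year) from the first event year,
optionally flattening after a plateau year. Presets:
`central_europe_historical` (200 stations, 1951–2018, 0.025 °C/yr — the
observed 0.25 °C/decade winter rate), `rcp45_like` (2010–2099, 0.04 °C/yr
to 2060 then flat; ≈ +2 °C by the 2090s) and `rcp85_like` (2010–2099,
0.053 °C/yr throughout; ≈ +4.5 °C). Warming is uniform over the year by
default; a `winter_factor` knob can weight November–February.

**Phenology.** Onset dates are produced by the process model itself under a
*true* mechanism — by default `HR = 600 − 2·CA(C1)` with F1 forcing — plus
rounded N(0, 2 days) observation noise. The coefficients were chosen once
so that onsets fall in mid spring (mean ≈ day 115, SD ≈ 13 days across the
historical scenario), comparable to birch leaf-out records. Because
generation inverts the same rule the analysis fits, parameter recovery is a
genuine end-to-end check rather than a tautology: the discrete daily step,
the strict-inequality rule and the observation noise all intervene.

**What the generator does not emulate.** Spatial correlation between
stations (locations are independent draws), weather extremes beyond
Gaussian AR(1), species differences (one synthetic species), observation
biases of volunteer networks, and resampled analogue weather. Passing tests
therefore demonstrate the internal consistency and statistical behaviour of
the chain under a known mechanism — not the reproduction of any real-data
estimate.

## Problem sizes and numerical choices

The package's own validation runs at deliberately modest scales:

* The valid/invalid partition check uses 100 stations × 60 years
  (≈ 6,000 records, warming 0.04 °C/yr). At that size the pooled
  correlations of the boundary models sit far from zero relative to their
  sampling error, so the partition — exactly the five threshold-and-triangle
  models C1, C2, C4, C5, C12 valid, the other seven invalid — is stable
  across seeds.
* Oracle-equivalence checks (vectorized accumulation vs. a per-day loop;
  optimized onset search vs. a brute-force double loop) use 100 random
  season instances each, at tolerance 1e−9 or exact integer equality.
* Coefficient-recovery coverage uses 100 replicates of n = 500 records
  (direct `HR = 500 − 2·CA + N(0, 20)` draws), requiring both 95% Wald
  intervals to cover in at least 93 of 100.
* Projections use the 30-station scenario presets over 2010–2099; the
  historical trend-pattern check uses the 200-station preset.

Numerical conventions worth knowing: temperature scan grids are snapped to
exact hundredths of a degree (`round(seq(...), 2)`) so that breakpoint
temperatures like 6.90 or 36.00 are hit exactly rather than missed by
floating-point accumulation in `seq()`; regression p-values on exactly
collinear toy inputs are handled explicitly (an exact zero-residual line
has p = 0 for a nonzero slope, p = 1 for a zero one); and all stochastic
components draw from explicit seeds carried inside scenario and mechanism
objects, with no hidden global RNG state (`withr::with_seed`).

## Known limitations

* The dynamic model C9 is applied at daily rather than hourly resolution
  (consistent with the rest of the suite), so its absolute portion counts
  are smaller than horticultural chill-portion values computed hourly.
* The "NetCDF-style" gridded reader ingests a CF-like long-format text
  table (`date, lat, lon, tmean[, tmax, tmin]`) with nearest-cell
  extraction, not binary NetCDF.
* Nonlinear (e.g. exponential) CA–HR forms are out of scope by design; the
  linear form is the fitted and simulated rule.
* Station-level verdicts apply no multiple-testing correction across
  stations; each station is reported as its own test.

## A compact end-to-end run

```{r, eval = FALSE}
cfg <- pipeline_config(
  scenario = climate_scenario(25, 1994:2018, warming_rate = 0.04, seed = 1),
  mechanism = mechanism_spec(seed = 2),
  out_dir = tempfile("phenochill_run")
)
res <- run_pipeline(cfg)
subset(res$validity, verdict == "valid")$chilling_model
res$fits[res$fits$chilling_model == "C1", ]
```
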