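---
title: "The fixed cohort bias: models, simulators and the trimming rule"
author: "fixedcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fixed cohort bias: models, simulators and the trimming rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixedcohort)
```

## The problem

A retrospective birth cohort is usually assembled by taking *all births
between a fixed start and end date*. Pregnancies differ in length, so the
population at risk is distorted at both edges of such a window:

* a pregnancy conceived more than the *minimum observable gestation* before
  the start date is captured only if it lasted long enough to deliver inside
  the window — short gestations are silently missing;
* a pregnancy conceived less than the *maximum observable gestation* before
  the end date is captured only if it delivered before the window closed —
  long gestations are silently missing.

These missing births are not censored observations: they are subjects whose
start *and* end are unknown and who simply never enter the data. The
consequence is an artificial seasonal pattern in gestation length by month
of conception — and biased estimates for any seasonal exposure, such as
temperature — even when the underlying data carry no signal at all. We call
this the *fixed cohort bias*.

The package treats the two observable extremes as parameters
(`gestation_bounds()`, default 19 and 43 completed weeks = 133 and 301 days
at a fixed 7 days/week conversion; they are an empirical property of the
registry at hand and therefore configurable).

## The correction

`trim_fixed_cohort_bias()` restricts a fixed cohort to conceptions between
`g_min` days before the window start and `g_max` days before the window end
(all interval ends inclusive; we read "from 1 July 2005 to 30 June 2009" as
a closed interval). Inside that conception interval every gestation length
in `[g_min, g_max]` delivers inside the window, so no conception date has
selectively missing gestations. The arithmetic guarantees this, and a
property test asserts it on random inputs. The price is sample size: for a
four-year window the trim removes about 11.5% of the fixed cohort.

A special case needs no correction: when the end date's day-and-month falls
just before the start's day-and-month ("matching" dates, e.g. 1 July 2005 to
30 June 2009), the long-gestation excess at the start and the
short-gestation excess at the end fall on the same calendar months and
cancel — for purely calendar-periodic predictors such as conception month.
The cancellation does *not* hold for time-dependent exposures, which is why
the trim matters even for well-chosen windows.

## The simulators

`simulate_null_cohort()` reproduces the null design used to exhibit the
bias: conception dates i.i.d. discrete-uniform by day from `g_max` days
before the window start (for the default window, 3 September 2004) through
the window end, and gestation lengths i.i.d. from a `gestation_sampler()`,
independent of conception date. Nothing in the raw data is seasonal; any
seasonal structure that appears after `apply_fixed_window()` is pure
selection.

The default sampler is a normal distribution with mean 272 d and SD 16 d,
discretized to whole days and truncated to `[133, 301]` d — matching a mean
(SD) of 38.8 (2.3) weeks. Truncation at 43 weeks shrinks the realized SD to
about 2.1 weeks; we keep the parent parameters rather than inflating them,
since the target moments are themselves registry summaries. An `empirical`
sampler resamples a user-supplied pool of gestation lengths with
replacement, which is what one would use with a real cohort in hand.

Two generators inject known signal for parameter-recovery experiments:

* `simulate_seasonal_cohort()` multiplies the sampler's discrete daily
  hazard `h(d) = P(G = d | G >= d)` by `exp(shift_m)` for conceptions in
  month `m` (clamped at 1, with forced absorption at `g_max` so the
  distribution stays proper). This is a discrete-time proportional-hazards
  transform, so the Cox model used downstream is correctly specified under
  the alternative and a fitted log-HR should recover `shift_m`. With all
  shifts zero the generator is byte-identical to the null simulator under
  the same seed (both draw through one shared inverse-CDF path).
* `simulate_temperature_cohort()` walks each pregnancy day by day and
  multiplies the baseline hazard by `exp(gamma * (T_roll - T_ref) / 10)`,
  where `T_roll` is the trailing 28-day mean temperature at the current
  calendar date. It supplies ground truth for the time-dependent pipeline.

`generate_weather()` produces the daily series: a sinusoid
`mean + amplitude * cos(2*pi*(doy - phase)/365.25)` plus Gaussian noise,
and humidity analogously (clamped to [0, 100]%). Defaults (mean 21 °C,
amplitude 5 °C, peak in mid-January, noise SD 1.5 °C; humidity 70% ± 8%)
emulate a subtropical southern-hemisphere climate whose annual mean matches
the 21 °C reference temperature. Leap days take the value of their
day-of-year; the 365.25-day period keeps the phase from drifting.

What the synthetic data deliberately do **not** emulate: secular trends and
weekday structure in conceptions, the left skew of real gestation
distributions, registry covariates correlated with season (race, maternal
age), spatial variation in exposure, and pregnancies ending before 19 weeks
(not registered at all). Passing tests therefore demonstrate the selection
mechanism and the correctness of the estimators, not the size of the bias
in any particular registry.

## Estimation

All survival models run on the gestational-age time scale with every
pregnancy entering the risk set at day 0 — deliberately, with no
delayed-entry correction, because the analysis under study is the naive one
(the bias is *caused* by absent subjects, and the remedy studied here is
trimming, not truncation weighting). Every included pregnancy has an
observed birth, so there is no censoring machinery; the row schema still
carries an event flag.

* `monthly_hazard_profile()` fits 11 conception-month indicators with
  January as the reference, on one row per pregnancy. HR > 1 means a higher
  chance of giving birth at each gestational age, i.e. *shorter*
  gestations.
* `expand_counting_process()` splits each pregnancy's span `(0, G]` at the
  distinct observed gestation lengths (the event times — finer splits would
  add rows but not information to the partial likelihood) and evaluates the
  trailing 28-day mean temperature and humidity at calendar date
  `conception + stop` for each interval.
* `fit_ph()` wraps a Newton–Raphson maximization of the Cox partial
  likelihood (relative log-likelihood tolerance 1e-9, at most 50
  iterations, error on non-convergence). Breslow tie handling is the
  default — daily gestation data are heavily tied, and a 100-replicate
  calibration in this package's tests shows the Breslow estimator is
  unbiased for the injected effects with near-nominal CI coverage; Efron is
  available by flag. A covariate constant across the data raises an
  explicit non-identifiability error naming it.
* The temperature curve uses a cubic B-spline basis with 3 degrees of
  freedom and no interior knots over the observed exposure range (knots are
  not dictated by the 3-df choice, so we use none), *centered* by
  subtracting the basis row at the reference temperature (21 °C). Centering
  pins HR(21 °C) = 1 exactly with a zero-width interval, and the delta
  method on the linear predictor gives pointwise 95% bands elsewhere.
  Evaluation outside the basis boundary is an error, never silent
  extrapolation. Humidity enters as a single linear rolling-mean term.

All confidence intervals are Wald intervals on the log-hazard scale.

## The experiments

`end_date_sweep()` is the central negative control: simulate `R` null
cohorts, then move the study end date back one month at a time (day clamped
to the month's last valid day) and re-estimate the monthly profile on the
naive and trimmed cohorts. Replicate profiles are averaged on the log scale
(geometric mean — the natural symmetric average for ratios). Replicate `r`
uses seed `base_seed + r`, so each replicate is independently reproducible.

Flatness is judged by `flatness()`: the maximum over the 11 non-reference
months of `|mean log HR| / SE(mean across replicates)`, with 3 as the
cutoff. The reported `peak_month` is the month with the highest averaged HR
(the shortest gestations) — the feature that visibly tracks the end date
when the bias is present; the months of *depressed* HR are dominated by the
start-side selection, which does not move with the end date.

Desk-scale defaults are 20,000 pregnancies × 25 replicates, which resolve
the bias (|z| ≈ 10 at shifted end dates) while keeping a full sweep under a
minute; the original design (≈115,000 births × 100 cohorts × 12 end dates)
is available by raising the parameters.

`naive_vs_adjusted()` and `temperature_contrast()` run the month-of-
conception and temperature pipelines on the fixed vs trimmed cohorts from
the same raw pregnancies, reporting tidy tables (and retained fractions)
before any plotting.

## Numerical and design choices

* Dates are pure calendar dates; validation is eager, at construction.
* Week-to-day conversion is a fixed ×7; boundaries inclusive everywhere.
* The month of a conception date ignores the year.
* Discrete-uniform conception dates make the window-survival probability
  exactly `window length / support length` (1461/1762 ≈ 82.9% for the
  default window), which the simulator reproduces within Monte-Carlo error
  against an independently coded oracle.
* In the seasonal generator, clamping `h * exp(shift)` at 1 and forcing
  absorption at `g_max` keeps the pmf proper for shifts of either sign; for
  the small shifts of interest (|shift| ≤ 0.5) the clamp is active only
  where the baseline hazard is already near 1.
* Grid-search cross-checks of the partial likelihood use a coarse-to-fine
  enumeration (1e-2 then 1e-4), valid because the partial likelihood is
  concave in the coefficient.
* A known degenerate input: a study window shorter than `g_max - g_min`
  (168 days by default) leaves no valid conception interval and trimming
  errors out rather than returning an empty cohort.

## Limitations

* The package estimates hazard ratios only; translating effects to absolute
  gestation-length scales would require an accelerated-failure-time or
  pooled-logistic formulation, which is out of scope.
* The trim assumes the observable gestation bounds are known and constant
  over the study period.
* The time-dependent pipeline assumes the exposure series is complete over
  every lookback; there is no imputation.
* Counting-process expansion materializes roughly
  `n × (mean rank of G among event times)` rows; for cohorts above ~10^5
  pregnancies with daily ties this is memory-heavy, and thinning the event
  grid (at some loss of information) would be the first optimization.
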