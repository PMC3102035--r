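# fixedcohort

Tools for demonstrating, quantifying and removing the **fixed cohort bias**
in retrospective birth cohorts.

## The problem

Retrospective birth cohorts are usually defined as *all births between a
fixed start and end date*. Because pregnancies vary in length, such a window
silently misses:

- **short** gestations conceived more than the minimum observable gestation
  (default 19 weeks = 133 days) before the start date — only the long ones
  delivered inside the window;
- **long** gestations conceived less than the maximum observable gestation
  (default 43 weeks = 301 days) before the end date — only the short ones
  delivered in time.

The missing births distort the population at risk at both edges of the
window and manufacture a seasonal pattern in gestation length by month of
conception — and bias the estimated effect of any seasonal exposure such as
temperature — even when the data contain no signal at all.

The package is aimed at perinatal and environmental epidemiologists who work
with registry-based cohorts: it provides the bias mechanism as a Monte-Carlo
simulator, the correction, and the survival-analysis pipeline used around
both.

## The model

Gestation length (in days) is the survival time, and all models are Cox
proportional-hazards fits on the gestational-age scale. A hazard ratio above
1 means an increased chance of giving birth at each gestational age, hence
*shorter* gestations; below 1, *longer* gestations.

- **Seasonality**: `λ(t | month m) = λ₀(t) · exp(βₘ)`, with 11
  month-of-conception indicators and January as the reference.
- **Temperature**: a time-dependent exposure via counting-process rows
  `(start, stop]`. `λ(t) = λ₀(t) · exp(s(T₂₈(t))ᵀβ + γ·H₂₈(t))`, where
  `T₂₈`/`H₂₈` are the trailing 28-day mean temperature/humidity at the
  calendar date matching gestational day `t`, and `s(·)` is a cubic
  B-spline with 3 df, centered so the hazard ratio is exactly 1 at the
  21 °C reference.
- **The correction**: keep only conceptions in
  `[start − 133 d, end − 301 d]` (inclusive). Inside that interval, every
  observable gestation length delivers inside the window, so no conception
  date has selectively missing gestations.

## Worked example

```r
library(fixedcohort)

w <- study_window("2005-07-01", "2009-06-30")

# 20,000 pregnancies with NO seasonal signal: uniform conception dates,
# gestations drawn independently from a 38.8 (2.3)-week sampler
raw <- simulate_null_cohort(20000, w, seed = 42)

fixed    <- apply_fixed_window(raw, w)
#> fixed window: kept 16518 of 20000 births (3482 excluded)
adjusted <- trim_fixed_cohort_bias(fixed)
#> trim: retained 14614 of 16518 pregnancies (88.5%),
#>       conceptions in [2005-02-18, 2008-09-02]

# shorten the window end by 6 months and compare naive vs trimmed profiles
naive_vs_adjusted(raw, study_window("2005-07-01", "2008-12-30"))
#> <naive_vs_adjusted> fixed n = 14485, adjusted n = 12595 (87.0% retained)
#>  month hr_naive hr_adjusted
#>    Jan   1.0000      1.0000
#>    Feb   0.9961      0.9729
#>    Mar   1.0337      0.9712
#>    Apr   1.0286      0.9436
#>    ...
```

A single cohort is noisy; the bias shows up unmistakably when profiles are
averaged across replicates. `end_date_sweep()` runs the full experiment —
25 null cohorts, end dates 0/3/6 months before 30 June 2009, naive and
trimmed arms — and `flatness()` summarizes each profile by the maximum over
non-reference months of |mean log HR| / SE:

```r
sw <- end_date_sweep(w, n_per_cohort = 20000, n_replicates = 25,
                     month_offsets = c(0L, 3L, 6L), base_seed = 1)
flatness(sw)
#>        arm   end_date max_abs_z peak_month  flat
#> 1 adjusted 2009-06-30  2.151019          2  TRUE
#> 2 adjusted 2009-03-30  2.156178          2  TRUE
#> 3 adjusted 2008-12-30  2.150852          2  TRUE
#> 4    naive 2009-06-30  1.967177          2  TRUE
#> 5    naive 2009-03-30 11.213025          7 FALSE
#> 6    naive 2008-12-30 11.211297          4 FALSE
```

Reading the table: the data are null, yet the naive cohorts show a strong
artificial seasonal pattern (max |z| ≈ 11) for both shortened end dates,
with the month of shortest gestations (`peak_month`) moving as the end date
moves (July → April). The pattern vanishes (max |z| < 3) when the end
day-month sits just before the start day-month (30 June vs 1 July), and
trimming restores flatness for *every* end date at the cost of ~11.5% of
the sample.

`temperature_contrast()` runs the analogous naive-vs-adjusted comparison for
the time-dependent temperature curve; `plot()` methods draw the monthly
profiles, sweep panels and temperature curves.

A thin command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","fixedcohort.R",package="fixedcohort"))')" \
    simulate --n 20000 --seed 1 --out out/
```

with subcommands `simulate`, `trim`, `fit-season`, `fit-temperature`,
`sweep` and `plot`.

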