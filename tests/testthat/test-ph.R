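# Cox proportional-hazards fitting and the counting-process expansion.

test_that("Breslow fit matches the brute-force partial-likelihood oracle", {
  # fixed 4-subject example: event times 1..4, binary covariate; the
  # alternating pattern keeps the partial likelihood maximizer finite
  d <- data.frame(id = 1:4, start = 0, stop = 1:4, event = 1L,
                  x = c(1, 0, 1, 0))
  fit <- fit_ph(d, "x", ties = "breslow")
  b_oracle <- oracle_grid_search_beta(d$start, d$stop, d$event, d$x)
  expect_lt(abs(unname(fit$coef["x"]) - b_oracle), 1e-3)
  # random tiny datasets with ties
  set.seed(31415)
  for (i in 1:8) {
    n <- sample(8:20, 1)
    d <- oracle_tiny_dataset(n)
    fit <- fit_ph(d, "x", ties = "breslow")
    b_oracle <- oracle_grid_search_beta(d$start, d$stop, d$event, d$x)
    expect_lt(abs(unname(fit$coef["x"]) - b_oracle), 1e-3)
    # reported log partial likelihood equals the oracle's at the maximum
    expect_equal(fit$loglik,
                 oracle_breslow_loglik(unname(fit$coef["x"]), d$start, d$stop,
                                       d$event, d$x),
                 tolerance = 1e-6)
  }
})

test_that("fit diagnostics: identifiability, events, interval sanity", {
  d <- data.frame(id = 1:4, start = 0, stop = 1:4, event = 1L, x = 1)
  expect_error(fit_ph(d, "x"), "constant across all risk sets")
  d2 <- data.frame(id = 1:4, start = 0, stop = 1:4, event = 0L,
                   x = c(1, 0, 1, 0))
  expect_error(fit_ph(d2, "x"), "no events")
  d3 <- data.frame(id = 1, start = 2, stop = 1, event = 1L, x = 1)
  expect_error(fit_ph(d3, "x"), "start < stop")
  expect_error(fit_ph(d, "y"), "unknown covariate")
})

test_that("variance is symmetric PSD and CIs are exp(coef +/- 1.96 se)", {
  set.seed(99)
  d <- oracle_tiny_dataset(40)
  d$z <- rbinom(40, 1, 0.5)
  fit <- fit_ph(d, c("x", "z"))
  V <- vcov(fit)
  expect_equal(V, t(V))
  expect_true(all(eigen(V, only.values = TRUE)$values >= -1e-12))
  ci <- confint(fit)
  se <- sqrt(diag(V))
  expect_equal(unname(ci[, "upper"] - coef(fit)), unname(1.96 * se),
               tolerance = 1e-3)
})

test_that("null covariates reject at roughly the nominal rate", {
  # type-I check: independent covariate, |coef| < 3 SE in nearly all runs
  set.seed(2718)
  inside <- 0L
  for (r in 1:20) {
    n <- 800
    d <- data.frame(id = seq_len(n), start = 0,
                    stop = as.numeric(sample(250:290, n, TRUE)), event = 1L,
                    x = rnorm(n))
    fit <- fit_ph(d, "x")
    inside <- inside + (abs(fit$coef) < 3 * sqrt(diag(fit$vcov)))
  }
  expect_gte(inside, 19L) # 3 SE ~ 99.7% coverage
})

test_that("expansion splits at observed event times and conserves totals", {
  w <- study_window("2006-01-01", "2006-12-31")
  p <- pregnancies(c("2005-05-01", "2005-06-01", "2005-08-01"),
                   c(280L, 250L, 250L), sex = c(1, 0, 1))
  wx <- tiny_weather()
  rows <- expand_counting_process(p, wx, covariates = "sex")
  # one row per (pregnancy, event time <= G); cuts are {250, 280}
  expect_identical(nrow(rows), 2L + 1L + 1L)
  expect_identical(sum(rows$event), 3L)
  agg <- tapply(rows$stop - rows$start, rows$id, sum)
  expect_equal(as.numeric(agg[order(as.integer(names(agg)))]),
               c(280, 250, 250))
  # event row is the last interval of each pregnancy
  last <- rows[rows$event == 1L, ]
  expect_equal(last$stop, p$gestation_days)
  # fixed covariates repeat across a pregnancy's rows
  expect_equal(unique(rows$sex[rows$id == 1]), 1)
  # intervals are contiguous from 0
  for (i in 1:3) {
    ri <- rows[rows$id == i, ]
    expect_equal(ri$start, c(0, head(ri$stop, -1)))
  }
})

test_that("expansion agrees with survival::survSplit", {
  w <- default_window()
  p <- simulate_null_cohort(80, w, seed = 17)
  wx <- tiny_weather()
  rows <- expand_counting_process(p, wx, spec = NULL, humidity = FALSE)
  cuts <- sort(unique(p$gestation_days))
  suppressPackageStartupMessages(library(survival))
  ss <- survSplit(Surv(time, event) ~ id,
                  data = data.frame(id = p$id,
                                    time = p$gestation_days,
                                    event = 1L),
                  cut = cuts, start = "tstart", end = "time")
  ss <- ss[order(ss$id, ss$time), ]
  ours <- rows[order(rows$id, rows$stop), ]
  expect_equal(nrow(ours), nrow(ss))
  expect_equal(ours$start, ss$tstart)
  expect_equal(ours$stop, as.numeric(ss$time))
  expect_equal(ours$event, ss$event)
})

test_that("single-pregnancy cohort expands to a single event row", {
  p <- pregnancies("2005-03-01", 140L)
  rows <- expand_counting_process(p, tiny_weather(), spec = NULL)
  expect_identical(nrow(rows), 1L)
  expect_equal(rows$start, 0)
  expect_equal(rows$stop, 140)
  expect_identical(rows$event, 1L)
  expect_error(expand_counting_process(p[0, ], tiny_weather()), "empty")
})

test_that("with time-constant covariates, expansion is statistically a no-op", {
  w <- study_window("2006-01-01", "2007-12-31")
  p <- simulate_null_cohort(300, w, seed = 23)
  p$smoker <- rbinom(nrow(p), 1, 0.3)
  co <- apply_fixed_window(p, w, quiet = TRUE)
  # constant weather -> exposures constant -> only the fixed covariate varies
  dates <- seq(as.Date("2004-01-01"), as.Date("2008-12-31"), by = 1)
  wx <- weather_series(dates, temp_C = 21, humidity_pct = 70)
  rows <- expand_counting_process(co, wx, spec = NULL, covariates = "smoker")
  expect_true(all(rows$temp_mean == 21))
  fit_exp <- fit_ph(rows, "smoker")
  fit_flat <- fit_ph(as_counting_process(co, "smoker"), "smoker")
  expect_lt(abs(fit_exp$coef - fit_flat$coef), 1e-8)
  expect_lt(abs(fit_exp$loglik - fit_flat$loglik), 1e-6)
})
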