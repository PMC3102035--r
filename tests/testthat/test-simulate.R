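# Samplers, null/seasonal cohort simulators, and the weather generator.

test_that("sampler pmf lives on the bounded support with the configured moments", {
  b <- gestation_bounds()
  s <- gestation_sampler(bounds = b)
  expect_equal(sum(s$prob), 1)
  expect_identical(range(s$days), c(133L, 301L))
  mu <- sum(s$days * s$prob)
  sdv <- sqrt(sum((s$days - mu)^2 * s$prob))
  # defaults sit near a mean of 38.8 weeks; the SD of the truncated parent
  # (16 d) is shrunk by the 43-week cap, so the realized SD sits a little
  # below 2.3 weeks
  expect_lt(abs(mu / 7 - 38.8), 0.15)
  expect_lt(abs(sdv / 7 - 2.3), 0.25)
  # realized draws match the pmf moments within Monte-Carlo error
  w <- default_window()
  p <- simulate_null_cohort(50000, w, s, b, seed = 1234)
  expect_lt(abs(mean(p$gestation_days) - mu), 3 * sdv / sqrt(50000))
  expect_lt(abs(sd(p$gestation_days) - sdv), 0.3)
})

test_that("empirical sampler resamples its pool and respects bounds", {
  b <- gestation_bounds()
  pool <- c(200L, 200L, 250L, 280L)
  s <- gestation_sampler("empirical", pool = pool, bounds = b)
  w <- default_window()
  p <- simulate_null_cohort(300, w, s, b, seed = 5)
  expect_true(all(p$gestation_days %in% pool)) # sub-multiset of pool support
  expect_error(gestation_sampler("empirical", pool = c(100L, 200L), bounds = b),
               "outside")
})

test_that("simulated conception dates cover exactly the at-risk period", {
  w <- default_window()
  b <- gestation_bounds()
  p <- simulate_null_cohort(5000, w, seed = 11)
  expect_true(all(p$conception_date >= w$start - b$g_max_days))
  expect_true(all(p$conception_date <= w$end))
  # 43 weeks before 1 July 2005 is 3 September 2004
  expect_identical(format(w$start - b$g_max_days), "2004-09-03")
})

test_that("fixing the seed fixes the cohort; different seeds differ", {
  w <- default_window()
  a <- simulate_null_cohort(500, w, seed = 3)
  b2 <- simulate_null_cohort(500, w, seed = 3)
  c2 <- simulate_null_cohort(500, w, seed = 4)
  expect_identical(a, b2)
  expect_false(identical(a, c2))
})

test_that("window survival fraction matches a brute-force MC oracle", {
  w <- default_window()
  b <- gestation_bounds()
  n <- 200000L
  p <- simulate_null_cohort(n, w, seed = 21)
  frac <- nrow(apply_fixed_window(p, w, quiet = TRUE)$pregnancies) / n
  # oracle: independent generation route (rejection-sampled rounded normal,
  # different seed), direct birth-date arithmetic; 5x draws so the oracle's
  # own Monte-Carlo noise is small relative to the simulator's
  n_oracle <- 5L * n
  set.seed(987654)
  g <- integer(0)
  while (length(g) < n_oracle) {
    cand <- as.integer(round(rnorm(n_oracle, 272, 16)))
    g <- c(g, cand[cand >= b$g_min_days & cand <= b$g_max_days])
  }
  g <- g[seq_len(n_oracle)]
  first <- w$start - b$g_max_days
  conc <- first + sample.int(as.integer(w$end - first) + 1L, n_oracle, TRUE) - 1L
  births <- conc + g
  frac_oracle <- mean(births >= w$start & births <= w$end)
  se_diff <- sqrt(frac_oracle * (1 - frac_oracle) * (1 / n + 1 / n_oracle))
  expect_lt(abs(frac - frac_oracle), 3 * se_diff + 1e-12)
})

test_that("seasonal effect validates and reduces exactly to the null case", {
  expect_error(seasonal_effect(c(0.1, rep(0, 11))), "reference")
  expect_error(seasonal_effect(rep(0, 5)), "12")
  w <- default_window()
  eff0 <- seasonal_effect()
  expect_identical(simulate_seasonal_cohort(400, w, effect = eff0, seed = 8),
                   simulate_null_cohort(400, w, seed = 8))
})

test_that("a positive log-hazard shift shortens that month's gestations", {
  w <- default_window()
  shifts <- rep(0, 12)
  shifts[6] <- 0.4
  p <- simulate_seasonal_cohort(60000, w, effect = seasonal_effect(shifts),
                                seed = 13)
  m <- conception_month(p)
  expect_lt(mean(p$gestation_days[m == 6]), mean(p$gestation_days[m == 1]))
})

test_that("hazard-shift transform preserves probability mass", {
  s <- gestation_sampler()
  for (shift in c(-0.5, -0.1, 0.1, 0.5, 2)) {
    p <- fixedcohort:::shifted_pmf(s, shift)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("weather generator honours its closed forms and coverage", {
  # amplitude 0, noise 0 -> constant series at the mean
  w0 <- generate_weather("2005-01-01", "2005-03-31", amplitude = 0,
                         noise_sd = 0, humidity_amplitude = 0,
                         humidity_noise_sd = 0, seed = 1)
  expect_true(all(w0$temp_C == 21))
  expect_true(all(w0$humidity_pct == 70))
  # CLT bound on the long-run mean (zero amplitude isolates the noise)
  wn <- generate_weather("2000-01-01", "2009-12-31", amplitude = 0,
                         noise_sd = 2, seed = 2)
  n <- nrow(wn)
  expect_lt(abs(mean(wn$temp_C) - 21), 3 * 2 / sqrt(n))
  # reproducible
  expect_identical(wn, generate_weather("2000-01-01", "2009-12-31",
                                        amplitude = 0, noise_sd = 2, seed = 2))
  # humidity clamped to [0, 100]
  wh <- generate_weather("2005-01-01", "2005-12-31", mean_humidity = 95,
                         humidity_amplitude = 20, humidity_noise_sd = 10,
                         seed = 3)
  expect_true(all(wh$humidity_pct >= 0 & wh$humidity_pct <= 100))
})

test_that("weather validation rejects gaps and out-of-range humidity", {
  w <- generate_weather("2005-01-01", "2005-01-31", seed = 1)
  expect_error(validate_weather(w[-5, ]), "gap")
  w2 <- w
  w2$humidity_pct[3] <- 101
  expect_error(validate_weather(w2), "\\[0, 100\\]")
})

test_that("temperature-driven simulator responds in the right direction", {
  w <- study_window("2006-07-01", "2007-06-30")
  wx <- generate_weather("2005-06-01", "2008-07-31", noise_sd = 0.5, seed = 4)
  # gamma = 0 reduces to baseline-hazard simulation: same marginal mean as
  # the null sampler within MC error
  null <- simulate_temperature_cohort(4000, w, weather = wx, gamma = 0,
                                      seed = 5)
  s <- gestation_sampler()
  mu0 <- sum(s$days * s$prob)
  expect_lt(abs(mean(null$gestation_days) - mu0), 1)
  # under constant weather the hazard multiplier is uniform in time, so a
  # warmer-than-reference climate with gamma > 0 stochastically shortens
  # gestation relative to the reference climate
  dates <- seq(as.Date("2005-06-01"), as.Date("2008-07-31"), by = 1)
  wx26 <- weather_series(dates, temp_C = 26, humidity_pct = 70)
  wx21 <- weather_series(dates, temp_C = 21, humidity_pct = 70)
  hot <- simulate_temperature_cohort(4000, w, weather = wx26, gamma = 1.5,
                                     seed = 5)
  ref <- simulate_temperature_cohort(4000, w, weather = wx21, gamma = 1.5,
                                     seed = 5)
  expect_lt(mean(hot$gestation_days), mean(ref$gestation_days) - 2)
  # insufficient weather coverage is an error
  short_wx <- generate_weather("2006-01-01", "2007-01-31", seed = 4)
  expect_error(simulate_temperature_cohort(50, w, weather = short_wx,
                                           gamma = 0, seed = 1), "cover")
})
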