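# Fixed-window inclusion, trimming rule, and the cohort data model.

test_that("pregnancy validation is eager and names offending rows", {
  expect_error(pregnancies("2005-01-01", 0L), "sanity bound")
  expect_error(pregnancies("2005-01-01", 401L), "sanity bound")
  expect_error(pregnancies("not-a-date", 280L), "unparseable")
  expect_error(validate_pregnancies(data.frame(id = 1)), "missing column")
  p <- pregnancies(c("2005-01-01", "2005-03-01"), c(280L, 259L), sex = c(0, 1))
  expect_equal(birth_dates(p), as.Date(c("2005-10-08", "2005-11-15")))
  expect_equal(p$sex, c(0, 1))
})

test_that("study window and gestation bounds enforce their invariants", {
  expect_error(study_window("2005-12-31", "2005-01-01"), "start_date")
  expect_error(gestation_bounds(301, 133), "g_min_days < g_max_days")
  expect_error(gestation_bounds(0, 100), "g_min_days")
  b <- gestation_bounds()
  expect_identical(c(b$g_min_days, b$g_max_days), c(133L, 301L)) # 19/43 wk x 7
})

test_that("fixed window keeps exactly births inside the window, inclusive", {
  w <- study_window("2005-01-01", "2005-12-31")
  p <- pregnancies(
    c("2004-02-01", "2004-12-15", "2005-03-26", "2004-03-01"),
    c(280L, 140L, 280L, 250L) # births 2004-11-07, 2005-05-04, 2005-12-31, 2004-11-06
  )
  expect_message(apply_fixed_window(p, w), "excluded")
  co <- apply_fixed_window(p, w, quiet = TRUE)
  expect_s3_class(co, "cohort")
  expect_identical(co$provenance, "fixed")
  expect_identical(co$pregnancies$id, c(2L, 3L)) # order preserved
  expect_identical(co$n_excluded, 2L)
  # birth on the end date exactly is included (inclusive boundary)
  expect_true(as.Date("2005-12-31") %in% birth_dates(co))
  # empty result is a warning, not an error
  late <- pregnancies("2006-06-01", 280L)
  expect_warning(apply_fixed_window(late, w, quiet = TRUE), "empty")
})

test_that("trim boundaries match an independent calendar oracle", {
  w <- default_window()
  lo_oracle <- oracle_shift_date("2005-07-01", -133)
  hi_oracle <- oracle_shift_date("2009-06-30", -301)
  expect_identical(lo_oracle, "2005-02-18")
  expect_identical(hi_oracle, "2008-09-02")
  p <- pregnancies(
    c(lo_oracle, hi_oracle,
      oracle_shift_date(lo_oracle, -1), oracle_shift_date(hi_oracle, 1),
      "2008-12-01"),
    c(200L, 200L, 290L, 250L, 160L)
  )
  fixed <- apply_fixed_window(p, w, quiet = TRUE)
  expect_identical(nrow(fixed$pregnancies), 5L) # all births inside the window
  adj <- trim_fixed_cohort_bias(fixed, quiet = TRUE)
  expect_identical(adj$provenance, "adjusted")
  expect_identical(format(adj$conception_interval),
                   c(lo_oracle, hi_oracle))
  # boundary dates retained; one-day-outside and end-exclusion-zone removed
  expect_setequal(adj$pregnancies$id, c(1L, 2L))
})

test_that("trim requires a fixed cohort and a wide-enough window", {
  p <- pregnancies("2005-01-01", 280L)
  expect_error(trim_fixed_cohort_bias(structure(
    list(pregnancies = p, window = default_window(), provenance = "raw"),
    class = "cohort")), "provenance")
  # window shorter than g_max - g_min = 168 days -> empty conception interval
  short <- apply_fixed_window(p, study_window("2005-10-01", "2005-10-31"),
                              quiet = TRUE)
  expect_error(suppressWarnings(trim_fixed_cohort_bias(short, quiet = TRUE)),
               "empty")
})

test_that("conception_month extracts the calendar month, year ignored", {
  expect_identical(conception_month(as.Date("2004-09-15")), 9L)
  expect_identical(conception_month(as.Date("2008-12-31")), 12L)
  expect_identical(conception_month(as.Date("2005-01-01")), 1L)
  p <- pregnancies(c("2004-09-15", "2008-12-31"), c(280L, 280L))
  expect_identical(conception_month(p), c(9L, 12L))
})

test_that("trim is a subset of fixed, idempotent, and never re-checks births", {
  w <- default_window()
  b <- gestation_bounds()
  set.seed(7)
  for (rep in 1:3) {
    raw <- simulate_null_cohort(800, w, seed = 100 + rep)
    fixed <- apply_fixed_window(raw, w, quiet = TRUE)
    adj <- trim_fixed_cohort_bias(fixed, b, quiet = TRUE)
    # subset + monotone counts: |raw| >= |fixed| >= |adjusted|
    expect_true(all(adj$pregnancies$id %in% fixed$pregnancies$id))
    expect_true(nrow(raw) >= nrow(fixed$pregnancies))
    expect_true(nrow(fixed$pregnancies) >= nrow(adj$pregnancies))
    # idempotence
    adj2 <- trim_fixed_cohort_bias(adj, b, quiet = TRUE)
    expect_identical(adj2$pregnancies, adj$pregnancies)
    # any conception in the adjusted interval with gestation in [g_min, g_max]
    # has a birth date inside the window automatically
    lo <- w$start - b$g_min_days
    hi <- w$end - b$g_max_days
    conc <- sample(seq(lo, hi, by = "1 day"), 50, replace = TRUE)
    gest <- sample(b$g_min_days:b$g_max_days, 50, replace = TRUE)
    births <- conc + gest
    expect_true(all(births >= w$start & births <= w$end))
  }
})
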