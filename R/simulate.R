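# Synthetic cohorts: conception dates are drawn discrete-uniform over the
# full at-risk period (from g_max days before the window start through the
# window end), so that every birth date inside the window is reachable and the
# raw data carry no seasonal signal unless one is injected.

#' Per-month seasonal effect on the birth hazard
#'
#' Ground-truth log-hazard shifts by conception month, used to inject a known
#' seasonal signal for parameter-recovery experiments. The reference month's
#' shift must be exactly 0 so that fitted hazard ratios are directly
#' comparable to `exp(shift)`.
#'
#' @param shifts numeric vector of 12 log-hazard shifts (January..December).
#' @param reference_month index of the reference month (default 1, January).
#' @return an object of class `seasonal_effect`.
#' @export
#' @examples
#' seasonal_effect(c(0, 0, 0, 0, 0, 0.1, 0, 0, 0, 0, 0, 0)) # +0.1 in June
seasonal_effect <- function(shifts = rep(0, 12), reference_month = 1L) {
  shifts <- as.numeric(shifts)
  if (length(shifts) != 12L || anyNA(shifts)) {
    stop("`shifts` must be 12 non-missing log-hazard values", call. = FALSE)
  }
  reference_month <- as.integer(reference_month)
  if (shifts[reference_month] != 0) {
    stop("the reference month's shift must be exactly 0", call. = FALSE)
  }
  structure(list(shifts = shifts, reference_month = reference_month),
            class = "seasonal_effect")
}

# Shared engine: uniform conception dates + inverse-CDF gestation draws from
# (possibly month-shifted) pmfs. A single runif(n) vector drives the
# gestation draws, so the all-shifts-zero case is byte-identical to the null
# simulator under the same seed.
simulate_cohort_engine <- function(n, window, sampler, effect, bounds, seed) {
  stopifnot(n > 0, inherits(window, "study_window"),
            inherits(sampler, "gestation_sampler"),
            inherits(bounds, "gestation_bounds"))
  support <- sampler$days[sampler$prob > 0]
  if (min(support) < bounds$g_min_days || max(support) > bounds$g_max_days) {
    stop(sprintf("sampler support [%d, %d] violates gestation bounds [%d, %d]",
                 min(support), max(support),
                 bounds$g_min_days, bounds$g_max_days), call. = FALSE)
  }
  with_seed(seed, {
    first <- window$start - bounds$g_max_days
    n_days <- as.integer(window$end - first) + 1L
    conception <- first + (sample.int(n_days, n, replace = TRUE) - 1L)
    m <- month_of(conception)
    u <- runif(n)
    gest <- integer(n)
    cdfs <- lapply(effect$shifts, function(s) cumsum(shifted_pmf(sampler, s)))
    for (mm in sort(unique(m))) {
      idx <- which(m == mm)
      gest[idx] <- draw_from_cdf(u[idx], sampler$days, cdfs[[mm]])
    }
    pregnancies(conception_date = conception, gestation_days = gest)
  })
}

#' Simulate a null (no-seasonality) raw cohort
#'
#' Conception dates are i.i.d. discrete-uniform by day on
#' \[`window$start - g_max_days`, `window$end`\] and gestation lengths are
#' i.i.d. draws from the sampler, independent of conception date — so the raw
#' data have no seasonal pattern in gestation length or birth dates. Passing
#' the result through [apply_fixed_window()] then exhibits the fixed cohort
#' bias on purely non-seasonal data.
#'
#' @param n number of pregnancies to simulate (before windowing).
#' @param window the [study_window()] the cohort will later be restricted to.
#' @param sampler a [gestation_sampler()].
#' @param bounds a [gestation_bounds()].
#' @param seed integer seed; fixing it fixes the entire cohort.
#' @return a pregnancy table (raw, pre-windowing).
#' @export
#' @examples
#' w <- study_window("2005-07-01", "2009-06-30")
#' p <- simulate_null_cohort(500, w, seed = 1)
#' range(p$conception_date)
simulate_null_cohort <- function(n, window, sampler = gestation_sampler(),
                                 bounds = gestation_bounds(), seed = NULL) {
  simulate_cohort_engine(n, window, sampler, seasonal_effect(), bounds, seed)
}

#' Simulate a cohort with a known seasonal effect
#'
#' As [simulate_null_cohort()], but the discrete daily hazard of birth for a
#' pregnancy conceived in month \eqn{m} is multiplied by
#' \eqn{\exp(\mathrm{shift}_m)} (clamped at 1), i.e. a discrete-time
#' proportional-hazards transform of the baseline gestation distribution. A
#' positive shift raises the birth hazard and therefore shortens gestations.
#' With all shifts zero the output is identical to [simulate_null_cohort()]
#' under the same seed.
#'
#' @inheritParams simulate_null_cohort
#' @param effect a [seasonal_effect()].
#' @return a pregnancy table (raw, pre-windowing).
#' @export
simulate_seasonal_cohort <- function(n, window, sampler = gestation_sampler(),
                                     effect = seasonal_effect(),
                                     bounds = gestation_bounds(), seed = NULL) {
  stopifnot(inherits(effect, "seasonal_effect"))
  simulate_cohort_engine(n, window, sampler, effect, bounds, seed)
}

#' Simulate a cohort whose birth hazard depends on rolling-mean temperature
#'
#' Day-by-day simulation of gestation under a time-dependent exposure: at
#' gestational day \eqn{d} (calendar date conception + d) the baseline
#' discrete hazard from the sampler is multiplied by
#' \eqn{\exp(\gamma (T_{roll} - T_{ref}) / 10)}, where \eqn{T_{roll}} is the
#' mean temperature over the `lookback_days` ending that date. Used as ground
#' truth for recovering a known log-linear temperature effect with the
#' counting-process pipeline.
#'
#' @inheritParams simulate_null_cohort
#' @param weather a [weather_series()] covering every date from
#'   `window$start - g_max_days + g_min_days - lookback_days + 1` through
#'   `window$end + g_max_days` (the simulator checks and errors otherwise).
#' @param gamma log hazard ratio per 10 degC above the reference temperature.
#' @param reference_temp reference temperature in degC (default 21).
#' @param lookback_days exposure averaging window (default 28).
#' @return a pregnancy table (raw, pre-windowing).
#' @export
simulate_temperature_cohort <- function(n, window,
                                        sampler = gestation_sampler(),
                                        weather, gamma,
                                        reference_temp = 21,
                                        lookback_days = 28L,
                                        bounds = gestation_bounds(),
                                        seed = NULL) {
  stopifnot(n > 0, inherits(window, "study_window"),
            inherits(sampler, "gestation_sampler"),
            inherits(bounds, "gestation_bounds"))
  weather <- validate_weather(weather)
  roll <- rolling_series(weather$temp_C, lookback_days)
  h0 <- sampler_hazard(sampler)
  days <- sampler$days
  with_seed(seed, {
    first <- window$start - bounds$g_max_days
    n_days <- as.integer(window$end - first) + 1L
    conception <- first + (sample.int(n_days, n, replace = TRUE) - 1L)
    gest <- rep(NA_integer_, n)
    alive <- seq_len(n)
    origin <- weather$date[1L]
    for (k in seq_along(days)) {
      d <- days[k]
      idx <- as.integer(conception[alive] + d - origin) + 1L
      if (any(idx < lookback_days | idx > nrow(weather))) {
        stop("weather series does not cover every exposure lookback needed ",
             "by the simulation", call. = FALSE)
      }
      t_roll <- roll[idx]
      h <- pmin(1, h0[k] * exp(gamma * (t_roll - reference_temp) / 10))
      if (k == length(days)) h[] <- 1 # absorb at g_max
      born <- runif(length(alive)) < h
      gest[alive[born]] <- d
      alive <- alive[!born]
      if (!length(alive)) break
    }
    # hazard is 1 at the last support day, so everyone has given birth
    pregnancies(conception_date = conception, gestation_days = gest)
  })
}

#' Generate a synthetic daily weather series
#'
#' Daily mean temperature follows a sinusoid plus Gaussian noise,
#' \eqn{T(t) = \mu + A \cos(2\pi(\mathrm{doy}(t) - \phi)/365.25) + \epsilon},
#' and humidity analogously (clamped to \[0, 100\]). Defaults emulate a
#' subtropical southern-hemisphere climate with annual mean 21 degC and a
#' mid-January peak. Leap days take the temperature of their day-of-year.
#'
#' @param start,end first and last date of the series (inclusive).
#' @param mean_temp annual mean temperature, degC.
#' @param amplitude seasonal half-range of temperature, degC (>= 0).
#' @param phase_day day-of-year of the temperature peak.
#' @param noise_sd SD of daily Gaussian temperature noise, degC (>= 0).
#' @param mean_humidity,humidity_amplitude,humidity_phase_day,humidity_noise_sd
#'   the corresponding humidity parameters (percent).
#' @param seed integer seed.
#' @return a [weather_series()].
#' @export
#' @examples
#' w <- generate_weather("2005-01-01", "2005-12-31", seed = 1)
#' mean(w$temp_C)
generate_weather <- function(start, end,
                             mean_temp = 21, amplitude = 5, phase_day = 15,
                             noise_sd = 1.5,
                             mean_humidity = 70, humidity_amplitude = 8,
                             humidity_phase_day = 46, humidity_noise_sd = 5,
                             seed = NULL) {
  start <- as_iso_date(start)
  end <- as_iso_date(end)
  if (anyNA(c(start, end)) || start > end) {
    stop("generate_weather() needs valid dates with start <= end",
         call. = FALSE)
  }
  if (amplitude < 0 || noise_sd < 0 || humidity_amplitude < 0 ||
      humidity_noise_sd < 0) {
    stop("amplitude and noise SD parameters must be non-negative",
         call. = FALSE)
  }
  dates <- seq(start, end, by = "1 day")
  doy <- as.POSIXlt(dates)$yday + 1L
  with_seed(seed, {
    temp <- mean_temp + amplitude * cos(2 * pi * (doy - phase_day) / 365.25) +
      rnorm(length(dates), 0, noise_sd)
    hum <- mean_humidity +
      humidity_amplitude * cos(2 * pi * (doy - humidity_phase_day) / 365.25) +
      rnorm(length(dates), 0, humidity_noise_sd)
    weather_series(dates, temp, pmin(100, pmax(0, hum)))
  })
}

#' Daily weather series
#'
#' @param date consecutive calendar dates (no gaps).
#' @param temp_C daily mean temperature, degC.
#' @param humidity_pct daily mean relative humidity, percent, in \[0, 100\].
#' @return a `data.frame` of class `weather_series`.
#' @export
weather_series <- function(date, temp_C, humidity_pct) {
  df <- data.frame(date = as_iso_date(date),
                   temp_C = as.numeric(temp_C),
                   humidity_pct = as.numeric(humidity_pct))
  validate_weather(df)
}

#' Validate a weather series
#'
#' Checks consecutive gap-free dates, numeric temperatures, and humidity in
#' \[0, 100\].
#'
#' @param df a data frame with columns `date`, `temp_C`, `humidity_pct`.
#' @return the validated data frame with class `weather_series`.
#' @export
validate_weather <- function(df) {
  required <- c("date", "temp_C", "humidity_pct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("weather series is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$date <- as_iso_date(df$date)
  if (anyNA(df$date)) {
    stop("weather series contains unparseable dates", call. = FALSE)
  }
  if (nrow(df) > 1L && any(diff(df$date) != 1)) {
    gap <- which(diff(df$date) != 1)[1L]
    stop(sprintf("weather series has a date gap after %s",
                 format(df$date[gap])), call. = FALSE)
  }
  if (anyNA(df$temp_C)) {
    stop("weather series contains missing temperatures", call. = FALSE)
  }
  if (anyNA(df$humidity_pct) ||
      any(df$humidity_pct < 0 | df$humidity_pct > 100)) {
    stop("humidity must lie in [0, 100] percent", call. = FALSE)
  }
  class(df) <- c("weather_series", "data.frame")
  df
}
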