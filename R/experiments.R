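# The three computational experiments: the moving-end-date bias
# demonstration, the naive-vs-adjusted contrast, and the temperature-effect
# contrast. All emit tidy tables before any plotting.

#' Moving-end-date bias sweep
#'
#' Simulates `n_replicates` null cohorts (no seasonal signal), then for each
#' of `n_end_dates` study end dates (the base end date, then 1, 2, ... months
#' earlier, day clamped to month end) applies the fixed birth-date window and
#' estimates the monthly hazard profile; optionally repeats on trimmed
#' (bias-adjusted) cohorts. Hazard ratios are averaged across replicates on
#' the log scale (geometric mean). An artificial seasonal pattern appears for
#' every end date except the one whose day-and-month falls just before the
#' start's day-and-month ("matching" dates), and trimming removes it for all
#' end dates.
#'
#' Each replicate uses seed `base_seed + replicate`, so replicates are
#' independent and individually reproducible; the whole sweep is reproducible
#' from `(base_seed, parameters)`.
#'
#' @param window base [study_window()]; the sweep shortens its end date.
#' @param n_per_cohort pregnancies simulated per replicate (before
#'   windowing); default 20,000.
#' @param sampler a [gestation_sampler()].
#' @param bounds a [gestation_bounds()].
#' @param n_replicates number of simulated cohorts (default 25).
#' @param n_end_dates number of end dates, stepping back one month at a time
#'   (default 12).
#' @param month_offsets integer months to step the end date back; overrides
#'   `n_end_dates` (default `0:(n_end_dates - 1)`).
#' @param base_seed integer; replicate r uses seed `base_seed + r`.
#' @param ties tie-handling method.
#' @param trim also compute profiles on trimmed cohorts (default `TRUE`).
#' @return an object of class `end_date_sweep`: list with `summary` (tidy
#'   data frame: `arm`, `end_date`, `month`, `hr`, `ci_low`, `ci_high`,
#'   `mean_log_hr`, `se`, `z`, `n_reps`), `log_hr` (arm x end x month x
#'   replicate array), `end_dates`, `n_failed`, and the call parameters.
#' @seealso [flatness()]
#' @export
end_date_sweep <- function(window, n_per_cohort = 20000L,
                           sampler = gestation_sampler(),
                           bounds = gestation_bounds(),
                           n_replicates = 25L, n_end_dates = 12L,
                           month_offsets = NULL,
                           base_seed = 1L,
                           ties = c("breslow", "efron"),
                           trim = TRUE) {
  ties <- match.arg(ties)
  stopifnot(inherits(window, "study_window"), n_replicates >= 2L,
            n_end_dates >= 1L)
  if (is.null(month_offsets)) {
    month_offsets <- seq_len(n_end_dates) - 1L
  }
  n_end_dates <- length(month_offsets)
  end_dates <- do.call(c, lapply(as.integer(month_offsets),
                                 function(k) months_back(window$end, k)))
  arms <- if (trim) c("naive", "adjusted") else "naive"
  log_hr <- array(NA_real_,
                  dim = c(length(arms), n_end_dates, 12L, n_replicates),
                  dimnames = list(arms, format(end_dates), month.abb, NULL))
  n_failed <- matrix(0L, length(arms), n_end_dates,
                     dimnames = list(arms, format(end_dates)))
  for (r in seq_len(n_replicates)) {
    raw <- simulate_null_cohort(n_per_cohort, window, sampler, bounds,
                                seed = base_seed + r)
    for (k in seq_len(n_end_dates)) {
      w_k <- study_window(window$start, end_dates[k])
      fixed <- apply_fixed_window(raw, w_k, quiet = TRUE)
      for (arm in arms) {
        co <- if (arm == "naive") fixed else {
          trim_fixed_cohort_bias(fixed, bounds, quiet = TRUE)
        }
        prof <- tryCatch(
          suppressWarnings(monthly_hazard_profile(co, ties = ties)),
          error = function(e) NULL)
        if (is.null(prof)) {
          n_failed[arm, k] <- n_failed[arm, k] + 1L
        } else {
          log_hr[arm, k, , r] <- prof$log_hr
        }
      }
    }
  }
  if (sum(n_failed) > 0L) {
    warning(sum(n_failed), " replicate fit(s) failed and were excluded from ",
            "the averages", call. = FALSE)
  }
  summ <- do.call(rbind, lapply(arms, function(arm) {
    do.call(rbind, lapply(seq_len(n_end_dates), function(k) {
      lh <- log_hr[arm, k, , , drop = TRUE] # 12 x R
      n_ok <- rowSums(!is.na(lh))
      mean_log <- rowMeans(lh, na.rm = TRUE)
      se <- apply(lh, 1L, sd, na.rm = TRUE) / sqrt(pmax(1L, n_ok))
      data.frame(arm = arm, end_date = end_dates[k], month = 1:12,
                 hr = exp(mean_log),
                 ci_low = exp(mean_log - 1.96 * se),
                 ci_high = exp(mean_log + 1.96 * se),
                 mean_log_hr = mean_log, se = se,
                 z = ifelse(se > 0, mean_log / se, NA_real_),
                 n_reps = n_ok,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, log_hr = log_hr, end_dates = end_dates,
                 n_failed = n_failed,
                 params = list(window = window, n_per_cohort = n_per_cohort,
                               n_replicates = n_replicates,
                               n_end_dates = n_end_dates,
                               base_seed = base_seed, ties = ties,
                               bounds = bounds)),
            class = "end_date_sweep")
}

#' Flatness diagnostics for an end-date sweep
#'
#' For each arm and end date, the maximum over the 11 non-reference months of
#' `|mean log HR| / SE(mean)` across replicates, plus the month of maximal
#' deviation. A profile is considered flat when `max_abs_z < 3`; an
#' artificial seasonal pattern announces itself as `max_abs_z` far above 3.
#'
#' @param sweep an [end_date_sweep()] result.
#' @return a data frame with columns `arm`, `end_date`, `max_abs_z`,
#'   `peak_month` (the month with the highest averaged HR, i.e. the shortest
#'   gestations — the feature that tracks the end date when the bias is
#'   present), `flat`.
#' @export
flatness <- function(sweep) {
  stopifnot(inherits(sweep, "end_date_sweep"))
  s <- sweep$summary[sweep$summary$month != 1L, ]
  out <- do.call(rbind, lapply(split(s, list(s$arm, format(s$end_date)),
                                     drop = TRUE), function(d) {
    z <- abs(d$z)
    data.frame(arm = d$arm[1L], end_date = d$end_date[1L],
               max_abs_z = max(z, na.rm = TRUE),
               peak_month = d$month[which.max(d$mean_log_hr)],
               stringsAsFactors = FALSE)
  }))
  out$flat <- out$max_abs_z < 3
  out <- out[order(out$arm, -as.numeric(out$end_date)), ]
  rownames(out) <- NULL
  out
}

#' @export
print.end_date_sweep <- function(x, ...) {
  p <- x$params
  cat(sprintf("<end_date_sweep> %d end dates x %d replicates x %d pregnancies (%s ties)\n",
              p$n_end_dates, p$n_replicates, p$n_per_cohort, p$ties))
  cat(sprintf("  start %s; end dates %s back to %s\n",
              format(p$window$start), format(x$end_dates[1L]),
              format(x$end_dates[length(x$end_dates)])))
  if (sum(x$n_failed)) {
    cat(sprintf("  %d failed replicate fit(s) excluded\n", sum(x$n_failed)))
  }
  cat("Flatness by arm and end date (max |mean log HR| / SE over months):\n")
  print(flatness(x), row.names = FALSE)
  invisible(x)
}

#' Plot an end-date sweep
#'
#' One panel per end date showing the replicate-averaged monthly hazard
#' ratios with 95% CIs of the mean, for the naive (black) and, if computed,
#' adjusted (grey) arms.
#'
#' @param x an `end_date_sweep`.
#' @param arms which arms to draw.
#' @param ... unused.
#' @export
plot.end_date_sweep <- function(x, arms = dimnames(x$log_hr)[[1L]], ...) {
  ends <- x$end_dates
  nk <- length(ends)
  mf <- c(ceiling(nk / 4), min(4L, nk))
  old <- par(mfrow = mf, mar = c(2.5, 2.5, 2, 0.5), mgp = c(1.5, 0.5, 0))
  on.exit(par(old), add = TRUE)
  s <- x$summary
  ylim <- range(s$ci_low, s$ci_high, 1, na.rm = TRUE)
  cols <- c(naive = "black", adjusted = "grey50")
  for (k in seq_len(nk)) {
    plot(NA, xlim = c(1, 12), ylim = ylim, xlab = "", ylab = "HR",
         main = format(ends[k], "%b %Y"), xaxt = "n")
    axis(1, at = c(1, 4, 7, 10), labels = month.abb[c(1, 4, 7, 10)])
    abline(h = 1, lty = 3)
    for (arm in arms) {
      d <- s[s$arm == arm & s$end_date == ends[k], ]
      points(d$month, d$hr, pch = 16, col = cols[[arm]], cex = 0.7)
      segments(d$month, d$ci_low, d$month, d$ci_high, col = cols[[arm]])
    }
  }
  invisible(x)
}

#' Naive vs adjusted monthly hazard profiles
#'
#' Runs [monthly_hazard_profile()] on the fixed-window cohort and on the same
#' cohort after [trim_fixed_cohort_bias()], from the same raw pregnancies.
#'
#' @param pregnancies_raw a raw pregnancy table (e.g. from
#'   [simulate_null_cohort()] or [read_cohort_csv()]).
#' @param window a [study_window()].
#' @param bounds a [gestation_bounds()].
#' @param ties tie-handling method.
#' @return an object of class `naive_adjusted`: list with `naive` and
#'   `adjusted` hazard profiles, `n_fixed`, `n_adjusted`,
#'   `retained_fraction`.
#' @export
naive_vs_adjusted <- function(pregnancies_raw, window,
                              bounds = gestation_bounds(),
                              ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  fixed <- apply_fixed_window(pregnancies_raw, window, quiet = TRUE)
  adjusted <- trim_fixed_cohort_bias(fixed, bounds, quiet = TRUE)
  structure(list(
    naive = monthly_hazard_profile(fixed, ties = ties),
    adjusted = monthly_hazard_profile(adjusted, ties = ties),
    n_fixed = nrow(fixed$pregnancies),
    n_adjusted = nrow(adjusted$pregnancies),
    retained_fraction = adjusted$retained_fraction,
    window = window, bounds = bounds
  ), class = "naive_adjusted")
}

#' @export
print.naive_adjusted <- function(x, ...) {
  cat(sprintf("<naive_vs_adjusted> fixed n = %d, adjusted n = %d (%.1f%% retained)\n",
              x$n_fixed, x$n_adjusted, 100 * x$retained_fraction))
  tab <- data.frame(month = month.abb,
                    hr_naive = round(x$naive$hr, 4),
                    hr_adjusted = round(x$adjusted$hr, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.naive_adjusted <- function(x, ...) {
  ylim <- range(x$naive$ci_low, x$naive$ci_high,
                x$adjusted$ci_low, x$adjusted$ci_high, 1, na.rm = TRUE)
  plot(x$naive$month - 0.12, x$naive$hr, xlim = c(1, 12), ylim = ylim,
       pch = 16, xaxt = "n", xlab = "Month of conception",
       ylab = "Hazard ratio", main = "Naive (black) vs adjusted (grey)")
  axis(1, at = 1:12, labels = month.abb)
  segments(x$naive$month - 0.12, x$naive$ci_low,
           x$naive$month - 0.12, x$naive$ci_high)
  points(x$adjusted$month + 0.12, x$adjusted$hr, pch = 16, col = "grey50")
  segments(x$adjusted$month + 0.12, x$adjusted$ci_low,
           x$adjusted$month + 0.12, x$adjusted$ci_high, col = "grey50")
  abline(h = 1, lty = 3)
  invisible(x)
}

#' Naive vs adjusted temperature effect curves
#'
#' The full time-dependent-exposure pipeline on both arms: fixed birth-date
#' window (plus trimming for the adjusted arm), counting-process expansion
#' against the weather series, Cox fit of the centered temperature spline
#' (adjusted for rolling-mean humidity by default), and curve extraction over
#' a temperature grid.
#'
#' @inheritParams naive_vs_adjusted
#' @param weather a [weather_series()].
#' @param spec a [spline_basis_spec()]; its boundary is resolved per arm from
#'   that arm's observed exposures.
#' @param grid temperature grid for the curves; default 41 points over the
#'   adjusted arm's resolved boundary intersected with the naive arm's.
#' @param covariates extra time-fixed adjustment covariate columns.
#' @param lookback_days exposure lookback (default 28).
#' @param humidity adjust for rolling-mean humidity (default `TRUE`).
#' @return an object of class `temperature_contrast`: list with `naive` and
#'   `adjusted` hazard profiles over temperature, the two `ph_fit`s, the two
#'   resolved specs, `retained_fraction`.
#' @export
temperature_contrast <- function(pregnancies_raw, window,
                                 bounds = gestation_bounds(),
                                 weather,
                                 spec = spline_basis_spec(),
                                 grid = NULL,
                                 covariates = NULL,
                                 lookback_days = 28L,
                                 humidity = TRUE,
                                 ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  fixed <- apply_fixed_window(pregnancies_raw, window, quiet = TRUE)
  adjusted <- trim_fixed_cohort_bias(fixed, bounds, quiet = TRUE)
  run_arm <- function(cohort) {
    rows <- expand_counting_process(cohort, weather, spec = spec,
                                    covariates = covariates,
                                    lookback_days = lookback_days,
                                    humidity = humidity)
    sp <- attr(rows, "spline_spec")
    covs <- c(paste0("temp_sp", seq_len(sp$df)),
              if (humidity) "humidity_mean", covariates)
    fit <- fit_ph(rows, covariates = covs, ties = ties)
    list(fit = fit, spec = sp)
  }
  naive_arm <- run_arm(fixed)
  adj_arm <- run_arm(adjusted)
  if (is.null(grid)) {
    lo <- max(naive_arm$spec$boundary[1], adj_arm$spec$boundary[1])
    hi <- min(naive_arm$spec$boundary[2], adj_arm$spec$boundary[2])
    grid <- sort(unique(c(seq(lo, hi, length.out = 41L), spec$reference)))
  }
  structure(list(
    naive = temperature_effect_curve(naive_arm$fit, naive_arm$spec, grid),
    adjusted = temperature_effect_curve(adj_arm$fit, adj_arm$spec, grid),
    fit_naive = naive_arm$fit, fit_adjusted = adj_arm$fit,
    spec_naive = naive_arm$spec, spec_adjusted = adj_arm$spec,
    n_fixed = nrow(fixed$pregnancies),
    n_adjusted = nrow(adjusted$pregnancies),
    retained_fraction = adjusted$retained_fraction
  ), class = "temperature_contrast")
}

#' @export
print.temperature_contrast <- function(x, ...) {
  cat(sprintf("<temperature_contrast> fixed n = %d, adjusted n = %d (%.1f%% retained)\n",
              x$n_fixed, x$n_adjusted, 100 * x$retained_fraction))
  cat("Adjusted-arm curve:\n")
  print.data.frame(head(as.data.frame(x$adjusted)[, c("temp_C", "hr", "ci_low", "ci_high")], 8),
                   digits = 4, row.names = FALSE)
  cat("  ... (", nrow(x$adjusted), "grid points )\n")
  invisible(x)
}

#' @export
plot.temperature_contrast <- function(x, ...) {
  old <- par(mfrow = c(1, 2))
  on.exit(par(old), add = TRUE)
  plot(x$naive, main = "Original cohort")
  plot(x$adjusted, main = "Adjusted cohort")
  invisible(x)
}
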