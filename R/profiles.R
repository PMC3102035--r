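# Hazard profiles: estimated hazard ratios with 95% CIs over months of
# conception or a temperature grid, pinned to 1 at the reference level.

new_hazard_profile <- function(df, axis, reference, fit = NULL) {
  structure(df, axis = axis, reference = reference, fit = fit,
            class = c("hazard_profile", "data.frame"))
}

#' Month-of-conception hazard profile
#'
#' Fits a Cox proportional-hazards model of gestation length (in days) on 11
#' conception-month indicators with January as the reference month, on
#' unexpanded one-row-per-pregnancy data (no time-dependent covariates), and
#' returns the 12 hazard ratios with Wald 95% confidence intervals. January's
#' HR is exactly 1 with a degenerate CI. A month absent from the data gets an
#' `NA` row (with a warning).
#'
#' @param x a `cohort` or pregnancy table with at least two distinct
#'   conception months; January must be present (it is the reference).
#' @param ties tie-handling method for [fit_ph()].
#' @return a `hazard_profile` data frame with columns `month`, `label`,
#'   `hr`, `ci_low`, `ci_high`, `log_hr`, `se`; the underlying `ph_fit` is
#'   attached as attribute `"fit"`.
#' @export
#' @examples
#' w <- study_window("2005-07-01", "2009-06-30")
#' p <- simulate_null_cohort(2000, w, seed = 1)
#' co <- apply_fixed_window(p, w, quiet = TRUE)
#' monthly_hazard_profile(co)
monthly_hazard_profile <- function(x, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  p <- as_pregnancies(x)
  if (!nrow(p)) {
    stop("cohort is empty", call. = FALSE)
  }
  m <- month_of(p$conception_date)
  present <- sort(unique(m))
  if (length(present) < 2L) {
    stop("need at least 2 distinct conception months", call. = FALSE)
  }
  if (!1L %in% present) {
    stop("January (the reference month) is absent from the cohort",
         call. = FALSE)
  }
  rows <- data.frame(id = p$id, start = 0,
                     stop = as.numeric(p$gestation_days), event = 1L)
  other <- setdiff(present, 1L)
  cols <- sprintf("month_%02d", other)
  for (k in seq_along(other)) {
    rows[[cols[k]]] <- as.numeric(m == other[k])
  }
  fit <- fit_ph(rows, covariates = cols, ties = ties)
  log_hr <- se <- rep(NA_real_, 12L)
  log_hr[1L] <- 0
  se[1L] <- 0
  log_hr[other] <- fit$coef[cols]
  se[other] <- sqrt(diag(fit$vcov))[cols]
  if (length(present) < 12L) {
    warning("conception month(s) absent from the cohort: ",
            paste(setdiff(1:12, present), collapse = ", "),
            "; their hazard ratios are NA", call. = FALSE)
  }
  df <- data.frame(
    month = 1:12,
    label = month.abb,
    hr = exp(log_hr),
    ci_low = exp(log_hr - 1.96 * se),
    ci_high = exp(log_hr + 1.96 * se),
    log_hr = log_hr,
    se = se,
    stringsAsFactors = FALSE
  )
  new_hazard_profile(df, axis = "month", reference = 1L, fit = fit)
}

#' Hazard-ratio curve over a temperature grid
#'
#' Extracts the exposure-response curve implied by the spline coefficients of
#' a fitted counting-process model: `HR(t) = exp(B(t) beta_spline)` with
#' pointwise 95% CIs from the delta method on the linear predictor
#' (`se(t) = sqrt(B(t) V B(t)')`). At the reference temperature the basis row
#' is zero, so HR = 1 exactly with a zero-width CI.
#'
#' @param fit a `ph_fit` whose covariates include the spline columns
#'   `temp_sp1..` produced with the same `spec`.
#' @param spec the resolved [spline_basis_spec()] used in the expansion
#'   (attribute `"spline_spec"` of the expanded rows).
#' @param grid temperature values (degC) at which to evaluate the curve; must
#'   lie within the spec's boundary. Default: 41 equally spaced points over
#'   the boundary.
#' @return a `hazard_profile` data frame with columns `temp_C`, `hr`,
#'   `ci_low`, `ci_high`, `log_hr`, `se`.
#' @export
temperature_effect_curve <- function(fit, spec, grid = NULL) {
  stopifnot(inherits(fit, "ph_fit"), inherits(spec, "spline_basis_spec"))
  if (is.null(spec$boundary)) {
    stop("`spec` must be resolved (boundary set); use the spline_spec ",
         "attribute of the expanded rows", call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- sort(unique(c(seq(spec$boundary[1], spec$boundary[2],
                              length.out = 41L), spec$reference)))
  }
  spline_cols <- paste0("temp_sp", seq_len(spec$df))
  absent <- setdiff(spline_cols, names(fit$coef))
  if (length(absent)) {
    stop("fit does not contain spline coefficient(s): ",
         paste(absent, collapse = ", "),
         "; was it produced with this spec?", call. = FALSE)
  }
  B <- spline_basis(grid, spec)
  beta <- fit$coef[spline_cols]
  V <- fit$vcov[spline_cols, spline_cols, drop = FALSE]
  eta <- drop(B %*% beta)
  se <- sqrt(pmax(0, rowSums((B %*% V) * B)))
  df <- data.frame(
    temp_C = grid,
    hr = exp(eta),
    ci_low = exp(eta - 1.96 * se),
    ci_high = exp(eta + 1.96 * se),
    log_hr = eta,
    se = se
  )
  new_hazard_profile(df, axis = "temperature", reference = spec$reference,
                     fit = fit)
}

#' @export
print.hazard_profile <- function(x, digits = 4, ...) {
  axis <- attr(x, "axis")
  cat(sprintf("Hazard profile over %s (reference: %s; HR > 1 means shorter gestations)\n",
              axis,
              if (axis == "month") month.abb[attr(x, "reference")]
              else paste0(attr(x, "reference"), " degC")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Plot a hazard profile
#'
#' Monthly profiles are drawn as points with vertical 95% CI segments;
#' temperature profiles as a curve with a shaded 95% band. The dotted
#' horizontal line at 1 marks no change in gestation length.
#'
#' @param x a `hazard_profile`.
#' @param ylim y-axis limits (default: covers the CIs).
#' @param main plot title.
#' @param ... passed to the underlying plot call.
#' @export
plot.hazard_profile <- function(x, ylim = NULL, main = NULL, ...) {
  axis_type <- attr(x, "axis")
  ok <- !is.na(x$hr)
  if (is.null(ylim)) {
    ylim <- range(x$ci_low[ok], x$ci_high[ok], 1)
  }
  if (axis_type == "month") {
    plot(x$month[ok], x$hr[ok], xlim = c(1, 12), ylim = ylim, xaxt = "n",
         xlab = "Month of conception", ylab = "Hazard ratio", pch = 16,
         main = main %||% "Seasonal pattern in gestation length", ...)
    axis(1, at = 1:12, labels = month.abb)
    segments(x$month[ok], x$ci_low[ok], x$month[ok], x$ci_high[ok])
  } else {
    plot(x$temp_C, x$hr, type = "n", ylim = ylim,
         xlab = "Mean temperature over last 4 weeks (degC)",
         ylab = "Hazard ratio",
         main = main %||% "Temperature and gestation length", ...)
    polygon(c(x$temp_C, rev(x$temp_C)), c(x$ci_low, rev(x$ci_high)),
            col = adjustcolor("grey", 0.5), border = NA)
    lines(x$temp_C, x$hr, lwd = 2)
    abline(v = attr(x, "reference"), lty = 3)
  }
  abline(h = 1, lty = 3)
  invisible(x)
}
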