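# Counting-process expansion for time-dependent exposures: each pregnancy's
# gestational span (0, G] is split at the distinct observed gestation lengths
# in the cohort (the event times), and within each interval the rolling-mean
# weather exposures are evaluated at the calendar date conception + stop.

#' Expand a cohort into counting-process rows with time-dependent exposures
#'
#' Splits every pregnancy's gestational-age span `(0, G]` at the distinct
#' gestation lengths observed in the cohort, so that covariates may change
#' value between consecutive event times, and attaches at each interval's
#' `stop` day: the rolling-mean temperature (`temp_mean`) and, optionally,
#' rolling-mean humidity (`humidity_mean`) evaluated at calendar date
#' `conception_date + stop`, plus the centered spline basis of the
#' temperature exposure (`temp_sp1..temp_spdf`). Time-fixed covariates are
#' repeated across a pregnancy's rows.
#'
#' Expansion preserves events (exactly one event row per pregnancy, its last)
#' and total pregnancy-time.
#'
#' @param cohort a `cohort` or pregnancy table.
#' @param weather a [weather_series()] covering every needed lookback.
#' @param spec a [spline_basis_spec()]; an unresolved boundary is resolved
#'   from the observed temperature exposures (union the reference) and the
#'   resolved spec is attached to the result as attribute `"spline_spec"`.
#'   Pass `NULL` to skip spline columns (the raw `temp_mean` is still
#'   attached).
#' @param covariates names of time-fixed covariate columns to carry along.
#' @param lookback_days trailing exposure window in days (default 28, i.e.
#'   "the last four weeks").
#' @param humidity attach rolling-mean humidity as well (default `TRUE`).
#' @return a data frame of counting-process rows (`id`, `start`, `stop`,
#'   `event`, exposures, spline columns, covariates) with attributes
#'   `spline_spec` and `lookback_days`.
#' @export
expand_counting_process <- function(cohort, weather,
                                    spec = spline_basis_spec(),
                                    covariates = NULL,
                                    lookback_days = 28L,
                                    humidity = TRUE) {
  p <- as_pregnancies(cohort)
  if (!nrow(p)) {
    stop("cohort is empty; nothing to expand", call. = FALSE)
  }
  weather <- validate_weather(weather)
  g <- p$gestation_days
  cuts <- sort(unique(g))
  n_rows_per <- findInterval(g, cuts) # number of cuts <= G_i
  i <- rep(seq_len(nrow(p)), n_rows_per)
  stop_day <- cuts[sequence(n_rows_per)]
  start_day <- c(0L, cuts)[sequence(n_rows_per)]
  out <- data.frame(
    id = p$id[i],
    start = as.numeric(start_day),
    stop = as.numeric(stop_day),
    event = as.integer(stop_day == g[i]),
    stringsAsFactors = FALSE
  )
  at_date <- p$conception_date[i] + stop_day
  out$temp_mean <- rolling_mean_exposure(weather, at_date, lookback_days,
                                         what = "temp")
  if (humidity) {
    out$humidity_mean <- rolling_mean_exposure(weather, at_date, lookback_days,
                                               what = "humidity")
  }
  if (!is.null(spec)) {
    spec <- resolve_spline_spec(spec, out$temp_mean)
    out <- cbind(out, as.data.frame(spline_basis(out$temp_mean, spec)))
  }
  if (!is.null(covariates)) {
    absent <- setdiff(covariates, names(p))
    if (length(absent)) {
      stop("unknown covariate column(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    for (v in covariates) out[[v]] <- p[[v]][i]
  }
  attr(out, "spline_spec") <- spec
  attr(out, "lookback_days") <- as.integer(lookback_days)
  out
}
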