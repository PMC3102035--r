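# Rolling-mean exposures over a daily weather series.

# Trailing rolling mean of a daily series; positions with an incomplete
# lookback are NA.
rolling_series <- function(x, window_days) {
  window_days <- as.integer(window_days)
  stopifnot(window_days >= 1L)
  as.numeric(stats::filter(x, rep(1 / window_days, window_days), sides = 1))
}

#' Rolling-mean exposure ending on a given date
#'
#' Arithmetic mean of the `window_days` daily values ending at (and including)
#' `on_date` — the "mean exposure in the last four weeks" with the default
#' 28-day window. Errors if any day of the lookback is missing from the
#' series.
#'
#' @param weather a [weather_series()].
#' @param on_date calendar date(s) at which the exposure is evaluated
#'   (vectorized).
#' @param window_days length of the trailing window in days (default 28).
#' @param what which variable to average: `"temp"` (degC) or `"humidity"`
#'   (percent).
#' @return numeric vector of rolling means, one per `on_date`.
#' @export
#' @examples
#' w <- weather_series(seq(as.Date("2005-01-01"), by = 1, length.out = 60),
#'                     temp_C = 21, humidity_pct = 70)
#' rolling_mean_exposure(w, as.Date("2005-02-15"))
rolling_mean_exposure <- function(weather, on_date, window_days = 28L,
                                  what = c("temp", "humidity")) {
  weather <- validate_weather(weather)
  what <- match.arg(what)
  on_date <- as_iso_date(on_date)
  if (anyNA(on_date)) {
    stop("`on_date` contains unparseable dates", call. = FALSE)
  }
  idx <- as.integer(on_date - weather$date[1L]) + 1L
  bad <- idx < window_days | idx > nrow(weather)
  if (any(bad)) {
    stop(sprintf(paste0(
      "weather series (%s to %s) does not cover the %d-day lookback ",
      "ending %s"), format(weather$date[1L]),
      format(weather$date[nrow(weather)]), window_days,
      format(on_date[which(bad)[1L]])), call. = FALSE)
  }
  col <- if (what == "temp") weather$temp_C else weather$humidity_pct
  rolling_series(col, window_days)[idx]
}
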