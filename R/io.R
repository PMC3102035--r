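# CSV readers/writers for cohort and weather tables, and run configuration
# serialization. All files are UTF-8 with a header row; dates are ISO-8601.

#' Read a cohort CSV
#'
#' Expects columns `id`, `conception_date` (ISO-8601 `YYYY-MM-DD`),
#' `gestation_days` (integer); any further columns are carried along as
#' covariates. Malformed rows are reported with their line numbers (header is
#' line 1). A file with a header but no rows yields an empty cohort with a
#' warning.
#'
#' @param path file path.
#' @return a validated pregnancy table.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  required <- c("id", "conception_date", "gestation_days")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) {
    warning("cohort CSV has a header but no rows: empty cohort",
            call. = FALSE)
    return(data.frame(id = character(), conception_date = as.Date(character()),
                      gestation_days = integer(), stringsAsFactors = FALSE))
  }
  line_no <- seq_len(nrow(df)) + 1L # header is line 1
  dates <- as_iso_date(df$conception_date)
  if (anyNA(dates)) {
    stop("unparseable conception_date in ", path, " at line(s): ",
         paste(head(line_no[is.na(dates)], 10L), collapse = ", "),
         call. = FALSE)
  }
  g <- suppressWarnings(as.numeric(df$gestation_days))
  bad_g <- is.na(g) | g != round(g)
  if (any(bad_g)) {
    stop("non-integer gestation_days in ", path, " at line(s): ",
         paste(head(line_no[bad_g], 10L), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = df$id, conception_date = dates,
                    gestation_days = as.integer(g), stringsAsFactors = FALSE)
  for (v in setdiff(names(df), required)) {
    num <- suppressWarnings(as.numeric(df[[v]]))
    out[[v]] <- if (anyNA(num)) df[[v]] else num # numeric if fully parseable
  }
  validate_pregnancies(out)
}

#' Write a cohort CSV
#'
#' Writes `id, conception_date, gestation_days` plus covariates with
#' ISO-8601 dates; the write/read round trip is the identity.
#'
#' @param x a pregnancy table or cohort.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  p <- as_pregnancies(x)
  p$conception_date <- format(p$conception_date, "%Y-%m-%d")
  write.csv(p, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a weather CSV
#'
#' Expects columns `date` (ISO-8601), `temp_C`, `humidity_pct`; the dates
#' must be consecutive with no gaps and humidity within \[0, 100\].
#'
#' @param path file path.
#' @return a [weather_series()].
#' @export
read_weather_csv <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_weather(df)
}

#' Write a weather CSV
#'
#' @param weather a [weather_series()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(weather, path) {
  weather <- validate_weather(weather)
  out <- as.data.frame(weather)
  out$date <- format(out$date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Run configuration
#'
#' Bundles every parameter of an analysis run into one serializable object so
#' a run's configuration can be written alongside its outputs.
#'
#' @param window a [study_window()].
#' @param bounds a [gestation_bounds()].
#' @param n,replicates,n_end_dates,seed simulation parameters.
#' @param sampler a [gestation_sampler()].
#' @param ties,spline_df,reference_temp,lookback_days model options.
#' @param out_dir output directory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(window, bounds = gestation_bounds(),
                       n = 20000L, replicates = 25L, n_end_dates = 12L,
                       seed = 1L, sampler = gestation_sampler(),
                       ties = "breslow", spline_df = 3L,
                       reference_temp = 21, lookback_days = 28L,
                       out_dir = ".") {
  structure(list(
    window = list(start = format(window$start), end = format(window$end)),
    bounds = list(g_min_days = bounds$g_min_days,
                  g_max_days = bounds$g_max_days),
    simulation = list(n = n, replicates = replicates,
                      n_end_dates = n_end_dates, seed = seed,
                      sampler = list(kind = sampler$kind,
                                     mean_days = sampler$mean_days,
                                     sd_days = sampler$sd_days)),
    model = list(ties = ties, spline_df = spline_df,
                 reference_temp = reference_temp,
                 lookback_days = lookback_days),
    out_dir = out_dir
  ), class = "run_config")
}

#' Write a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path file path (conventionally `config.json` next to the outputs).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration
#'
#' @param path path to a JSON file written by [write_run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  window: %s to %s; bounds %d/%d days\n",
              x$window$start, x$window$end,
              x$bounds$g_min_days, x$bounds$g_max_days))
  cat(sprintf("  simulation: n = %s, replicates = %s, end dates = %s, seed = %s\n",
              x$simulation$n, x$simulation$replicates,
              x$simulation$n_end_dates, x$simulation$seed))
  cat(sprintf("  model: %s ties, spline df %s, ref %s degC, lookback %s d\n",
              x$model$ties, x$model$spline_df, x$model$reference_temp,
              x$model$lookback_days))
  invisible(x)
}

#' Write the tidy table of a sweep or profile result as CSV
#'
#' @param x an `end_date_sweep`, `hazard_profile`, `naive_adjusted` or
#'   `temperature_contrast`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  tab <- if (inherits(x, "end_date_sweep")) {
    x$summary
  } else if (inherits(x, "hazard_profile")) {
    as.data.frame(x)
  } else if (inherits(x, c("naive_adjusted", "temperature_contrast"))) {
    rbind(cbind(arm = "naive", as.data.frame(x$naive)),
          cbind(arm = "adjusted", as.data.frame(x$adjusted)))
  } else {
    stop("don't know how to tabulate an object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  if ("end_date" %in% names(tab)) tab$end_date <- format(tab$end_date)
  write.csv(tab, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
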