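# Data model: pregnancies, study windows, gestation bounds, cohorts, and the
# fixed-window / trimming operations that create and then correct the bias.

#' Construct a table of pregnancies
#'
#' A pregnancy is fully described by its conception date and its gestation
#' length in days; the birth date is always derived as
#' `conception_date + gestation_days` and never stored independently.
#' Additional columns (baby sex, maternal age, smoking, ...) are carried along
#' as covariates.
#'
#' @param conception_date calendar dates of conception (`Date` or ISO-8601
#'   strings).
#' @param gestation_days integer gestation lengths in days; must lie in the
#'   sanity interval \[1, 400\].
#' @param id identifiers, one per pregnancy (defaults to row numbers).
#' @param ... optional covariate vectors, recycled to the number of
#'   pregnancies.
#'
#' @return A `data.frame` with columns `id`, `conception_date`,
#'   `gestation_days` and any covariates, validated eagerly.
#' @seealso [birth_dates()], [apply_fixed_window()]
#' @export
#' @examples
#' p <- pregnancies(c("2005-01-10", "2005-06-01"), c(280L, 259L))
#' birth_dates(p)
pregnancies <- function(conception_date, gestation_days,
                        id = seq_along(gestation_days), ...) {
  df <- data.frame(
    id = id,
    conception_date = as_iso_date(conception_date),
    gestation_days = as.integer(gestation_days),
    stringsAsFactors = FALSE
  )
  covs <- list(...)
  for (nm in names(covs)) {
    df[[nm]] <- rep_len(covs[[nm]], nrow(df))
  }
  validate_pregnancies(df)
}

#' Validate a pregnancy table
#'
#' Checks the structural invariants of a pregnancy table: required columns,
#' parseable conception dates and integer gestation lengths within the
#' \[1, 400\] day sanity bound. Failures raise errors that list the offending
#' rows.
#'
#' @param df a data frame with at least `id`, `conception_date`,
#'   `gestation_days`.
#' @return the validated data frame (dates coerced to `Date`, gestations to
#'   integer), invisibly usable as input everywhere a pregnancy table is
#'   expected.
#' @export
validate_pregnancies <- function(df) {
  required <- c("id", "conception_date", "gestation_days")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("pregnancy table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$conception_date <- as_iso_date(df$conception_date)
  if (anyNA(df$conception_date)) {
    bad <- which(is.na(df$conception_date))
    stop("unparseable conception_date at row(s): ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  g_raw <- df$gestation_days
  g <- suppressWarnings(as.numeric(g_raw))
  non_int <- is.na(g) | g != round(g)
  if (any(non_int)) {
    stop("non-integer gestation_days at row(s): ",
         paste(head(which(non_int), 10L), collapse = ", "), call. = FALSE)
  }
  out_of_range <- g < 1 | g > 400
  if (any(out_of_range)) {
    stop("gestation_days outside the sanity bound [1, 400] at row(s): ",
         paste(head(which(out_of_range), 10L), collapse = ", "), call. = FALSE)
  }
  df$gestation_days <- as.integer(g)
  df
}

#' Derived birth dates
#'
#' @param x a pregnancy table or a [cohort].
#' @return `Date` vector, `conception_date + gestation_days`.
#' @export
birth_dates <- function(x) {
  p <- as_pregnancies(x)
  p$conception_date + p$gestation_days
}

#' Study window of birth dates
#'
#' The fixed interval of birth dates that defines cohort membership; both
#' endpoints are inclusive.
#'
#' @param start,end calendar dates (`Date` or ISO-8601 strings),
#'   `start <= end`.
#' @return an object of class `study_window`.
#' @export
#' @examples
#' study_window("2005-07-01", "2009-06-30")
study_window <- function(start, end) {
  start <- as_iso_date(start)
  end <- as_iso_date(end)
  if (anyNA(c(start, end))) {
    stop("study window dates must be valid ISO-8601 dates", call. = FALSE)
  }
  if (start > end) {
    stop("study window start_date must be <= end_date", call. = FALSE)
  }
  structure(list(start = start, end = end), class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("Study window: %s to %s (%d days, inclusive)\n",
              format(x$start), format(x$end),
              as.integer(x$end - x$start) + 1L))
  invisible(x)
}

#' Observable gestation bounds
#'
#' The minimum and maximum gestation length observable in the registry the
#' cohort is drawn from. These parameterize the trimming rule: conceptions
#' more than `g_min_days` before the window start may have been missed if
#' short, and conceptions less than `g_max_days` before the window end may
#' have been missed if long. Defaults are 19 and 43 completed weeks (133 and
#' 301 days, weeks x 7), the observed extremes in a large Australian registry;
#' they are configurable because they are an empirical property of the cohort
#' at hand, not universal constants.
#'
#' @param g_min_days,g_max_days integer day bounds, `0 < g_min < g_max`.
#' @return an object of class `gestation_bounds`.
#' @export
gestation_bounds <- function(g_min_days = 133L, g_max_days = 301L) {
  g_min_days <- as.integer(g_min_days)
  g_max_days <- as.integer(g_max_days)
  if (is.na(g_min_days) || is.na(g_max_days) ||
      g_min_days <= 0L || g_min_days >= g_max_days) {
    stop("gestation bounds require 0 < g_min_days < g_max_days", call. = FALSE)
  }
  structure(list(g_min_days = g_min_days, g_max_days = g_max_days),
            class = "gestation_bounds")
}

#' @export
print.gestation_bounds <- function(x, ...) {
  cat(sprintf("Gestation bounds: %d to %d days (%.1f to %.1f weeks)\n",
              x$g_min_days, x$g_max_days,
              x$g_min_days / 7, x$g_max_days / 7))
  invisible(x)
}

new_cohort <- function(pregnancies, window, provenance,
                       n_input = nrow(pregnancies), n_excluded = 0L,
                       extra = list()) {
  structure(
    c(list(pregnancies = pregnancies, window = window,
           provenance = provenance, n_input = n_input,
           n_excluded = n_excluded), extra),
    class = "cohort"
  )
}

#' Coerce to a pregnancy table
#'
#' @param x a pregnancy table (validated data frame) or a `cohort`.
#' @return the underlying pregnancy data frame.
#' @export
as_pregnancies <- function(x) {
  if (inherits(x, "cohort")) {
    return(x$pregnancies)
  }
  if (is.data.frame(x)) {
    return(validate_pregnancies(x))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as pregnancies", call. = FALSE)
}

#' Apply a fixed birth-date window
#'
#' The cohort-assembly step that causes the fixed cohort bias: retain exactly
#' the pregnancies whose (derived) birth date falls inside the study window,
#' both ends inclusive. Input order is preserved and the number of exclusions
#' is recorded on the returned cohort (and reported via `message()`).
#'
#' @param x a pregnancy table or cohort.
#' @param window a [study_window()].
#' @param quiet suppress the exclusion-count message.
#' @return a `cohort` with provenance `"fixed"`.
#' @export
#' @examples
#' p <- pregnancies(c("2004-02-01", "2004-12-15"), c(280L, 140L))
#' w <- study_window("2005-01-01", "2005-12-31")
#' apply_fixed_window(p, w)
apply_fixed_window <- function(x, window, quiet = FALSE) {
  p <- as_pregnancies(x)
  stopifnot(inherits(window, "study_window"))
  births <- p$conception_date + p$gestation_days
  keep <- births >= window$start & births <= window$end
  n_excluded <- sum(!keep)
  if (!quiet) {
    message(sprintf("fixed window: kept %d of %d births (%d excluded)",
                    sum(keep), length(keep), n_excluded))
  }
  if (!any(keep)) {
    warning("fixed window excluded every pregnancy; cohort is empty",
            call. = FALSE)
  }
  new_cohort(p[keep, , drop = FALSE], window, "fixed",
             n_input = nrow(p), n_excluded = n_excluded)
}

#' Remove the fixed cohort bias by trimming conception dates
#'
#' Restricts a fixed cohort to pregnancies whose conception dates lie between
#' `g_min_days` before the window start and `g_max_days` before the window
#' end (both ends inclusive). Inside that interval every gestation length in
#' \[g_min, g_max\] produces a birth date inside the window, so no conception
#' date has selectively missing gestation lengths and the artificial seasonal
#' pattern disappears. The cost is a loss of sample size, recorded as the
#' retained fraction.
#'
#' @param cohort a `cohort` with provenance `"fixed"` (or `"adjusted"`, in
#'   which case the operation is idempotent).
#' @param bounds a [gestation_bounds()].
#' @param quiet suppress the retained-fraction message.
#' @return a `cohort` with provenance `"adjusted"`; carries
#'   `retained_fraction` and the retained `conception_interval`.
#' @export
trim_fixed_cohort_bias <- function(cohort, bounds = gestation_bounds(),
                                   quiet = FALSE) {
  stopifnot(inherits(cohort, "cohort"), inherits(bounds, "gestation_bounds"))
  if (!cohort$provenance %in% c("fixed", "adjusted")) {
    stop("trim_fixed_cohort_bias() expects a cohort produced by ",
         "apply_fixed_window() (provenance \"fixed\")", call. = FALSE)
  }
  lo <- cohort$window$start - bounds$g_min_days
  hi <- cohort$window$end - bounds$g_max_days
  if (lo > hi) {
    stop(sprintf(paste0(
      "trimmed conception interval is empty: window is shorter than ",
      "g_max - g_min (%d days); start - g_min = %s > end - g_max = %s"),
      bounds$g_max_days - bounds$g_min_days, format(lo), format(hi)),
      call. = FALSE)
  }
  p <- cohort$pregnancies
  keep <- p$conception_date >= lo & p$conception_date <= hi
  retained <- if (nrow(p)) sum(keep) / nrow(p) else NA_real_
  if (!quiet) {
    message(sprintf(
      "trim: retained %d of %d pregnancies (%.1f%%), conceptions in [%s, %s]",
      sum(keep), nrow(p), 100 * retained, format(lo), format(hi)))
  }
  new_cohort(p[keep, , drop = FALSE], cohort$window, "adjusted",
             n_input = nrow(p), n_excluded = sum(!keep),
             extra = list(retained_fraction = retained,
                          conception_interval = c(lo, hi),
                          bounds = bounds))
}

#' Calendar month of conception
#'
#' @param x a `Date` vector, pregnancy table or cohort.
#' @return integer month indices 1..12 (year ignored). Month 1 (January) is
#'   the reference month in all seasonal hazard profiles.
#' @export
conception_month <- function(x) {
  if (inherits(x, "Date")) {
    return(month_of(x))
  }
  month_of(as_pregnancies(x)$conception_date)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %s> %d pregnancies", x$provenance, nrow(x$pregnancies)))
  cat(sprintf(" (window %s to %s)\n", format(x$window$start),
              format(x$window$end)))
  if (!is.null(x$retained_fraction) && !is.na(x$retained_fraction)) {
    cat(sprintf("  trim retained %.1f%% of the fixed cohort; conceptions in [%s, %s]\n",
                100 * x$retained_fraction,
                format(x$conception_interval[1]),
                format(x$conception_interval[2])))
  } else if (x$n_excluded > 0L) {
    cat(sprintf("  %d of %d input pregnancies excluded by the birth-date window\n",
                x$n_excluded, x$n_input))
  }
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  p <- object$pregnancies
  g <- p$gestation_days
  out <- list(
    provenance = object$provenance,
    n = nrow(p),
    n_input = object$n_input,
    n_excluded = object$n_excluded,
    gestation_mean_weeks = mean(g) / 7,
    gestation_sd_weeks = sd(g) / 7,
    gestation_range_days = range(g),
    conception_range = range(p$conception_date),
    months_present = sort(unique(month_of(p$conception_date)))
  )
  class(out) <- "summary.cohort"
  out
}

#' @export
print.summary.cohort <- function(x, ...) {
  cat(sprintf("Cohort (%s): n = %d (from %d input, %d excluded)\n",
              x$provenance, x$n, x$n_input, x$n_excluded))
  cat(sprintf("  gestation: mean %.1f wk, SD %.1f wk, range %d-%d days\n",
              x$gestation_mean_weeks, x$gestation_sd_weeks,
              x$gestation_range_days[1], x$gestation_range_days[2]))
  cat(sprintf("  conceptions: %s to %s, %d distinct months\n",
              format(x$conception_range[1]), format(x$conception_range[2]),
              length(x$months_present)))
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  x$pregnancies
}
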