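# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library calls never perturb a user's random number stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Strict ISO-8601 date coercion: anything that does not parse as YYYY-MM-DD
# becomes NA (callers decide whether NA is an error).
as_iso_date <- function(x) {
  if (inherits(x, "Date")) {
    return(x)
  }
  as.Date(as.character(x), format = "%Y-%m-%d", optional = TRUE)
}

# Subtract `k` calendar months from a date, clamping the day of month to the
# last valid day of the target month (e.g. 31 March - 1 month -> 28/29 Feb).
months_back <- function(date, k) {
  stopifnot(inherits(date, "Date"), length(date) == 1L, k >= 0L)
  lt <- as.POSIXlt(date)
  total <- lt$year * 12L + lt$mon - as.integer(k)
  year <- total %/% 12L
  mon <- total %% 12L
  first <- as.Date(sprintf("%04d-%02d-01", year + 1900L, mon + 1L))
  last_day <- as.integer(format(seq(first, by = "1 month", length.out = 2L)[2L] - 1L, "%d"))
  first + (min(lt$mday, last_day) - 1L)
}

month_of <- function(dates) {
  as.POSIXlt(dates)$mon + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
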