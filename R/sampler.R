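# Gestation-length samplers: a discrete distribution over whole days of
# gestation, either parametric (discretized truncated normal) or empirical
# (resampling a user-supplied pool with replacement).

#' Gestation-length sampler
#'
#' Defines the baseline distribution of gestation length in whole days on the
#' support \[`g_min_days`, `g_max_days`\]. The parametric form is a normal
#' distribution discretized to days and truncated to the support; the defaults
#' (mean 272 d, SD 16 d) match a mean (SD) of 38.8 (2.3) weeks. The empirical
#' form resamples a pool of observed gestation lengths with replacement, for
#' use when a real cohort's gestations are available.
#'
#' Internally every sampler is reduced to a probability mass function over
#' days, which also supplies the discrete daily hazard used by the
#' seasonal-effect and temperature-effect simulators.
#'
#' @param kind `"parametric"` or `"empirical"`.
#' @param mean_days,sd_days location and scale of the parametric normal, in
#'   days.
#' @param pool integer vector of gestation lengths (days) for the empirical
#'   sampler; must lie within `bounds`.
#' @param bounds a [gestation_bounds()] giving the support.
#' @return an object of class `gestation_sampler` with elements `days`
#'   (support) and `prob` (pmf).
#' @export
#' @examples
#' s <- gestation_sampler()
#' sum(s$prob) # 1
gestation_sampler <- function(kind = c("parametric", "empirical"),
                              mean_days = 272, sd_days = 16,
                              pool = NULL,
                              bounds = gestation_bounds()) {
  kind <- match.arg(kind)
  stopifnot(inherits(bounds, "gestation_bounds"))
  days <- seq.int(bounds$g_min_days, bounds$g_max_days)
  if (kind == "parametric") {
    if (sd_days <= 0) {
      stop("parametric sampler requires sd_days > 0", call. = FALSE)
    }
    prob <- pnorm(days + 0.5, mean_days, sd_days) -
      pnorm(days - 0.5, mean_days, sd_days)
    if (sum(prob) <= 0) {
      stop("parametric sampler has no mass on the gestation support",
           call. = FALSE)
    }
  } else {
    if (is.null(pool) || !length(pool)) {
      stop("empirical sampler requires a non-empty `pool` of gestation days",
           call. = FALSE)
    }
    pool <- as.integer(pool)
    if (anyNA(pool) || any(pool < bounds$g_min_days | pool > bounds$g_max_days)) {
      stop(sprintf("empirical pool contains gestations outside [%d, %d] days",
                   bounds$g_min_days, bounds$g_max_days), call. = FALSE)
    }
    prob <- tabulate(pool - bounds$g_min_days + 1L, nbins = length(days))
  }
  prob <- prob / sum(prob)
  structure(list(kind = kind, days = days, prob = prob, bounds = bounds,
                 mean_days = if (kind == "parametric") mean_days else NULL,
                 sd_days = if (kind == "parametric") sd_days else NULL),
            class = "gestation_sampler")
}

#' @export
print.gestation_sampler <- function(x, ...) {
  mu <- sum(x$days * x$prob)
  sdv <- sqrt(sum((x$days - mu)^2 * x$prob))
  cat(sprintf("<gestation_sampler: %s> support [%d, %d] d, mean %.1f d (%.1f wk), SD %.1f d\n",
              x$kind, min(x$days), max(x$days), mu, mu / 7, sdv))
  invisible(x)
}

# Discrete daily hazard of birth implied by the sampler's pmf:
# h(d) = P(G = d) / P(G >= d); by construction h = 1 at the last support day.
sampler_hazard <- function(sampler) {
  p <- sampler$prob
  surv_from <- rev(cumsum(rev(p))) # P(G >= d)
  h <- ifelse(surv_from > 0, p / surv_from, 1)
  h[length(h)] <- 1
  pmin(h, 1)
}

# Pmf of gestation length after multiplying the discrete daily hazard by
# exp(shift), clamped to 1. The hazard at the last support day is forced to 1
# so any mass that the (downshifted) hazard would push beyond g_max is
# absorbed there and the transformed pmf still sums to 1.
shifted_pmf <- function(sampler, shift) {
  if (shift == 0) {
    return(sampler$prob)
  }
  h <- pmin(1, sampler_hazard(sampler) * exp(shift))
  k <- length(h)
  h[k] <- 1
  surv_before <- cumprod(c(1, 1 - h[-k]))
  h * surv_before
}

# Inverse-CDF draw: smallest support day whose CDF reaches u.
draw_from_cdf <- function(u, days, cdf) {
  cdf[length(cdf)] <- 1
  days[findInterval(u, cdf, left.open = TRUE) + 1L]
}
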