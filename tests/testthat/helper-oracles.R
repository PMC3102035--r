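# Independent oracles used by the tests. These deliberately avoid the code
# paths (and where possible the libraries) they are checking.

# --- calendar arithmetic ----------------------------------------------------
# Shift an ISO date by k days using a hand-maintained days-in-month table,
# stepping one day at a time; independent of R's Date arithmetic.
oracle_shift_date <- function(iso, k) {
  y <- as.integer(substr(iso, 1, 4))
  m <- as.integer(substr(iso, 6, 7))
  d <- as.integer(substr(iso, 9, 10))
  days_in <- function(y, m) {
    leap <- (y %% 4 == 0 && y %% 100 != 0) || y %% 400 == 0
    c(31, if (leap) 29 else 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[m]
  }
  step <- sign(k)
  for (i in seq_len(abs(k))) {
    d <- d + step
    if (d < 1) {
      m <- m - 1L
      if (m < 1L) { m <- 12L; y <- y - 1L }
      d <- days_in(y, m)
    } else if (d > days_in(y, m)) {
      d <- 1L
      m <- m + 1L
      if (m > 12L) { m <- 1L; y <- y + 1L }
    }
  }
  sprintf("%04d-%02d-%02d", y, m, d)
}

# --- Breslow partial likelihood ---------------------------------------------
# Hand-written Breslow log partial likelihood for (start, stop] data with a
# single covariate, evaluated on a vector of beta values.
oracle_breslow_loglik <- function(beta, start, stop, event, x) {
  times <- sort(unique(stop[event == 1]))
  ll <- numeric(length(beta))
  for (t in times) {
    dead <- which(event == 1 & stop == t)
    risk <- which(start < t & stop >= t)
    denom <- colSums(exp(outer(x[risk], beta)))
    ll <- ll + sum(x[dead]) * beta - length(dead) * log(denom)
  }
  ll
}

# Grid-search maximizer of the Breslow partial likelihood over [-5, 5].
# Two-stage enumeration at step 1e-2 then 1e-4 around the coarse argmax;
# equivalent to a full 1e-4 grid because the partial likelihood is concave
# in beta.
oracle_grid_search_beta <- function(start, stop, event, x,
                                    lo = -5, hi = 5, step = 1e-4) {
  coarse <- seq(lo, hi, by = 1e-2)
  ll <- oracle_breslow_loglik(coarse, start, stop, event, x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(max(lo, b0 - 0.02), min(hi, b0 + 0.02), by = step)
  llf <- oracle_breslow_loglik(fine, start, stop, event, x)
  fine[which.max(llf)]
}

# Random small survival dataset with one continuous covariate and some tied
# event times; covariate effect beta_true on the exponential rate.
oracle_tiny_dataset <- function(n, beta_true = 0.5) {
  x <- rnorm(n)
  t <- ceiling(rexp(n, rate = exp(beta_true * x)) * 4) # ties via ceiling
  data.frame(id = seq_len(n), start = 0, stop = as.numeric(t), event = 1L,
             x = x)
}

# --- shared fixtures --------------------------------------------------------
default_window <- function() study_window("2005-07-01", "2009-06-30")

tiny_weather <- function(start = "2004-01-01", end = "2010-06-30",
                         seed = 99L, noise_sd = 1, amplitude = 5) {
  generate_weather(start, end, noise_sd = noise_sd, amplitude = amplitude,
                   seed = seed)
}
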