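# Shared fixtures, built in code.

# Exact scalar Kalman filter for the linear-Gaussian system
#   x_{k+1} = a x_k + w,  w ~ N(0, Q);   z_k = x_k + v,  v ~ N(0, R)
# Returns per-step analysis means/variances given observations z.
exact_kalman <- function(z, a, Q, R, m0, P0) {
  T <- length(z)
  m <- numeric(T); P <- numeric(T)
  mp <- m0; Pp <- P0
  for (k in seq_len(T)) {
    mf <- a * mp
    Pf <- a^2 * Pp + Q
    K <- Pf / (Pf + R)
    mp <- mf + K * (z[k] - mf)
    Pp <- (1 - K) * Pf
    m[k] <- mp; P[k] <- Pp
  }
  list(mean = m, var = P,
       forecast_mean = NULL)
}

# Linear-Gaussian evolution model in the EnKF contract (uses the global
# RNG, as required).
linear_gaussian_model <- function(a, Q) {
  function(x, t0, t1) {
    c(x = a * x[["x"]] + stats::rnorm(1, 0, sqrt(Q)))
  }
}

# Mean of the rounded-then-clamped lognormal by direct mass summation:
# P(batch = k) mass of exp(N(mu, sigma^2)) rounding to k, clamped to cap.
rounded_lognormal_mean <- function(mu, sigma, cap = Inf, kmax = 1e5) {
  k <- seq_len(min(cap, kmax))
  upper <- ifelse(k == cap, Inf, k + 0.5)
  lowz <- (log(pmax(k - 0.5, .Machine$double.eps)) - mu) / sigma
  p <- pnorm((log(upper) - mu) / sigma) - pnorm(lowz)
  p[1] <- p[1] + pnorm((log(0.5) - mu) / sigma)  # draws rounding below 1
  sum(k * p) / sum(p)
}

# Hourly intensity profile used by the daily-identification experiments:
# exponential rise at `growth` to `peak` at `peak_hour`, exponential decay
# at `decay` after it, floored overnight. The defaults mirror the scale of
# real high-street data: peaks of a few thousand and overnight counts in
# the single digits.
profile_intensity <- function(growth, decay, peak = 4500, peak_hour = 12,
                              floor = 5) {
  h <- 0:23
  up <- peak * exp(growth * (h - peak_hour))
  down <- peak * exp(-decay * (h - peak_hour))
  pmax(floor, ifelse(h <= peak_hour, up, down))
}
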