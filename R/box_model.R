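#' Immigration-death ("box") process parameters
#'
#' Parameters of the box model: people arrive in an area at a constant
#' average rate `alpha` and each person independently departs at per-capita
#' rate `beta`, so at occupancy `x` the total departure rate is `beta * x`.
#' The stationary distribution is Poisson with mean `gamma = alpha / beta`.
#'
#' @param alpha Arrival rate (events per unit time), `>= 0`.
#' @param beta Per-capita departure rate (per unit time), `> 0`.
#' @return An object of class `box_params`. The dimensionless ratio
#'   `gamma = alpha / beta` is available through [box_gamma()] and is always
#'   recomputed from the stored rates.
#' @examples
#' p <- box_params(50, 0.25)
#' box_gamma(p)  # 200
#' @export
box_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha < 0) stop("`alpha` must be non-negative")
  if (beta <= 0) stop("`beta` must be strictly positive")
  structure(list(alpha = alpha, beta = beta), class = "box_params")
}

#' @rdname box_params
#' @param params A `box_params` object.
#' @export
box_gamma <- function(params) {
  stopifnot(inherits(params, "box_params"))
  params$alpha / params$beta
}

#' @export
print.box_params <- function(x, ...) {
  cat(sprintf(
    "Immigration-death process: alpha = %g, beta = %g (gamma = %g)\n",
    x$alpha, x$beta, box_gamma(x)))
  invisible(x)
}

#' Simulate the box model exactly (Gillespie algorithm)
#'
#' Event-driven stochastic simulation of the immigration-death process.
#' Between events the path is piecewise constant; the value recorded at each
#' output time is the state carried forward from the last event at or before
#' that time.
#'
#' @param params A [box_params()] object.
#' @param x0 Initial count, a non-negative integer.
#' @param output_times Strictly increasing times (from time 0) at which the
#'   state is recorded.
#' @param seed Optional integer; if given, `set.seed(seed)` is called so the
#'   realization is reproducible and the seed is stored on the result.
#' @param max_events Safety cap on the number of simulated events.
#' @return An object of class `box_trajectory`: a list with `times`,
#'   `counts` (non-negative integers) and `seed`.
#' @examples
#' tr <- simulate_box(box_params(50, 0.25), x0 = 5, output_times = 0:15,
#'                    seed = 1)
#' tr$counts
#' @export
simulate_box <- function(params, x0, output_times, seed = NULL,
                         max_events = Inf) {
  stopifnot(inherits(params, "box_params"))
  if (length(x0) != 1L || !is.finite(x0) || x0 < 0 || x0 != round(x0))
    stop("`x0` must be a single non-negative integer")
  output_times <- as.numeric(output_times)
  if (length(output_times) < 1L || any(diff(output_times) <= 0) ||
      any(output_times < 0))
    stop("`output_times` must be non-negative and strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  counts <- box_gillespie_cpp(params$alpha, params$beta, as.integer(x0),
                              output_times, max_events)
  structure(list(times = output_times, counts = counts, seed = seed),
            class = "box_trajectory")
}

#' Closed-form mean of the box model
#'
#' The mean occupancy obeys the linear ODE `du/dt = alpha - beta * u`, with
#' solution `u(t) = gamma + (u0 - gamma) exp(-beta t)`, `gamma = alpha/beta`.
#' The mean relaxes monotonically towards the stationary value `gamma`.
#'
#' @param params A [box_params()] object.
#' @param u0 Initial mean count.
#' @param t Time(s), `>= 0`; vectorized.
#' @return Mean count at each `t`.
#' @export
mean_solution <- function(params, u0, t) {
  stopifnot(inherits(params, "box_params"), is.numeric(u0), is.numeric(t))
  if (any(t < 0)) stop("`t` must be non-negative")
  g <- box_gamma(params)
  g + (u0 - g) * exp(-params$beta * t)
}

#' Closed-form variance of the box model
#'
#' The variance obeys `dv/dt = alpha + beta u - 2 beta v`, giving
#' `v(t) = gamma + (u0 - gamma) e^{-beta t} + [v0 - gamma - (u0 - gamma)]
#' e^{-2 beta t}`. For a Poisson initial condition (`v0 = u0`) the bracketed
#' term vanishes and `v(t) = u(t)` for all `t`; as `t -> Inf`, `v -> gamma`.
#'
#' @inheritParams mean_solution
#' @param v0 Initial variance, `>= 0`.
#' @return Variance of the count at each `t`.
#' @export
variance_solution <- function(params, u0, v0, t) {
  stopifnot(inherits(params, "box_params"), is.numeric(v0))
  if (any(t < 0)) stop("`t` must be non-negative")
  if (any(v0 < 0)) stop("`v0` must be non-negative")
  g <- box_gamma(params)
  ebt <- exp(-params$beta * t)
  g + (u0 - g) * ebt + (v0 - g - (u0 - g)) * ebt^2
}

#' Count distribution on a truncated support
#'
#' @param probs Probabilities for counts `0..n_max`.
#' @param leak Probability mass lost past the truncation bound.
#' @return An object of class `count_distribution` with fields `probs`,
#'   `n_max` and `leak`; `sum(probs) + leak` is 1 up to integration error.
#' @export
count_distribution <- function(probs, leak = 0) {
  probs <- as.numeric(probs)
  if (any(probs < -1e-12)) stop("probabilities must be non-negative")
  probs[probs < 0] <- 0
  tot <- sum(probs) + leak
  if (abs(tot - 1) > 1e-6)
    stop(sprintf("probabilities + leak must sum to 1 (got %.8f)", tot))
  structure(list(probs = probs, n_max = length(probs) - 1L, leak = leak),
            class = "count_distribution")
}

#' @export
mean.count_distribution <- function(x, ...) {
  sum((seq_along(x$probs) - 1) * x$probs) / sum(x$probs)
}

#' Variance of a `count_distribution`
#' @param x A `count_distribution`.
#' @return The variance of the (renormalized) truncated distribution.
#' @export
distribution_variance <- function(x) {
  stopifnot(inherits(x, "count_distribution"))
  n <- seq_along(x$probs) - 1
  p <- x$probs / sum(x$probs)
  m <- sum(n * p)
  sum((n - m)^2 * p)
}

#' Integrate the master equation of the box model
#'
#' Forward-integrates the truncated linear system
#' `dp_n/dt = alpha p_{n-1} + beta (n+1) p_{n+1} - (alpha + beta n) p_n`
#' for `n = 0..n_max`, with an extra absorbing "leak" state that accumulates
#' the arrival flux out of state `n_max`, so total mass is conserved exactly
#' and the truncation error is observable. Integration uses a stiff-safe
#' solver on the tridiagonal generator ([deSolve::lsoda] with a banded
#' Jacobian).
#'
#' @param params A [box_params()] object.
#' @param p0 Initial distribution: a [count_distribution()] or a bare
#'   probability vector over counts `0..length(p0)-1`.
#' @param t Time to integrate to, `>= 0`.
#' @param n_max Truncation bound; default `gamma + 10 sqrt(gamma)` (at least
#'   covering the support of `p0` with the same headroom above it).
#' @param leak_tol Leak mass above which a warning is attached to the result.
#' @return A [count_distribution()] at time `t` with its recorded `leak`.
#' @examples
#' p0 <- count_distribution(dpois(0:40, 5) / sum(dpois(0:40, 5)))
#' p1 <- integrate_master_equation(box_params(50, 0.25), p0, t = 1)
#' @export
integrate_master_equation <- function(params, p0, t, n_max = NULL,
                                      leak_tol = 1e-8) {
  stopifnot(inherits(params, "box_params"), length(t) == 1L, t >= 0)
  if (!inherits(p0, "count_distribution")) p0 <- count_distribution(p0)
  g <- box_gamma(params)
  m0 <- mean(p0)
  if (is.null(n_max)) {
    top <- max(g, m0, p0$n_max)
    n_max <- ceiling(top + 10 * sqrt(max(top, 1)))
  }
  n_max <- max(n_max, p0$n_max)
  p <- c(p0$probs, rep(0, n_max - p0$n_max))
  if (t == 0)
    return(count_distribution(p, leak = p0$leak))

  alpha <- params$alpha
  beta <- params$beta
  n <- 0:n_max
  out_rate <- alpha + beta * n          # loss term per state
  y0 <- c(p, p0$leak)                   # last component: leak accumulator
  nn <- n_max + 1L
  deriv <- function(tt, y, parms) {
    pn <- y[seq_len(nn)]
    dp <- -out_rate * pn
    dp[-1] <- dp[-1] + alpha * pn[-nn]               # arrivals n-1 -> n
    dp[-nn] <- dp[-nn] + beta * n[-1] * pn[-1]       # departures n+1 -> n
    dleak <- alpha * pn[nn]                          # flux past n_max
    list(c(dp, dleak))
  }
  sol <- deSolve::lsoda(y0, times = c(0, t), func = deriv, parms = NULL,
                        jactype = "bandint", bandup = 1L, banddown = 1L,
                        rtol = 1e-10, atol = 1e-14, maxsteps = 5e5)
  y <- sol[nrow(sol), -1]
  probs <- pmax(y[seq_len(nn)], 0)
  leak <- max(y[nn + 1L], 0)
  res <- structure(list(probs = probs, n_max = n_max, leak = leak),
                   class = "count_distribution")
  if (leak > leak_tol) {
    warning(sprintf(
      "master-equation leak %.3e exceeds tolerance %.3e; increase n_max",
      leak, leak_tol))
    attr(res, "leak_warning") <- TRUE
  }
  res
}

#' Pooled stationary autocorrelation of box-model realizations
#'
#' Estimates the stationary autocorrelation `a_h` at the requested lags by
#' pooling pairs of observations `(x_t, x_{t+h})` across an ensemble of
#' realizations recorded on a common uniform time grid. For the
#' immigration-death process in equilibrium `a_h = exp(-beta h)`.
#'
#' @param counts Matrix of counts, one realization per row, columns on the
#'   common time grid.
#' @param times Uniform time grid (one entry per column of `counts`).
#' @param lags Non-negative lags; each must be a multiple of the grid step.
#' @param burn_in Time before which observations are discarded (default 0;
#'   `5 / beta`, i.e. five relaxation times, is a sound choice when starting
#'   away from equilibrium).
#' @return An object of class `autocorrelation_estimate`: list with `lags`,
#'   `values` and `n_realizations`.
#' @export
empirical_autocorrelation <- function(counts, times, lags, burn_in = 0) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(times), all(lags >= 0))
  dt <- diff(times)
  if (length(dt) < 1L || max(abs(dt - dt[1])) > 1e-8 * dt[1])
    stop("`times` must be a uniform grid")
  dt <- dt[1]
  keep <- times >= burn_in
  x <- counts[, keep, drop = FALSE]
  tt <- ncol(x)
  values <- vapply(lags, function(h) {
    li <- h / dt
    if (abs(li - round(li)) > 1e-8)
      stop(sprintf("lag %g is not a multiple of the grid step %g", h, dt))
    li <- as.integer(round(li))
    if (tt - li < 2L)
      stop(sprintf("fewer than 2 usable samples at lag %g", h))
    if (li == 0L) return(1)
    a <- as.vector(x[, seq_len(tt - li), drop = FALSE])
    b <- as.vector(x[, seq_len(tt - li) + li, drop = FALSE])
    stats::cor(a, b)
  }, numeric(1))
  structure(list(lags = lags, values = values,
                 n_realizations = nrow(counts)),
            class = "autocorrelation_estimate")
}
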