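#' Bivariate distribution of daily growth/decay rates
#'
#' @param mean Length-2 vector `(growth mean, decay mean)`.
#' @param cov `2 x 2` symmetric positive semi-definite covariance.
#' @return Object of class `rate_distribution`.
#' @export
rate_distribution <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  stopifnot(length(mean) == 2L, all(dim(cov) == 2L))
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-10)))
    stop("`cov` must be symmetric")
  if (any(eigen(cov, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    stop("`cov` must be positive semi-definite")
  structure(list(mean = stats::setNames(mean, c("growth", "decay")),
                 cov = cov), class = "rate_distribution")
}

#' Fit the daily growth/decay rate distribution from hourly counts
#'
#' For each day, the growth rate is the least-squares slope of the natural
#' log of the hourly counts over the morning phase (06:00-12:00 by
#' default), and the decay rate is the magnitude of the slope over the
#' afternoon phase (13:00-19:00). Counts are floored at 1 before logging.
#' The sample mean vector and covariance across days define the
#' distribution that the daily resampling scheme draws from. A two-point
#' endpoint gradient is available for a stricter reading of "gradient".
#'
#' @param series A weekday hourly `footfall_series`.
#' @param growth_hours,decay_hours Clock hours of the two phases.
#' @param method `"least-squares"` (default) or `"endpoints"` (two-point
#'   difference between the first and last hour of the phase).
#' @return A [rate_distribution()] with the per-day rates attached as
#'   attribute `"daily"`.
#' @export
fit_daily_rate_distribution <- function(series, growth_hours = 6:12,
                                        decay_hours = 13:19,
                                        method = c("least-squares",
                                                   "endpoints")) {
  stopifnot(inherits(series, "footfall_series"))
  method <- match.arg(method)
  day <- as.Date(series$timestamp, tz = "UTC")
  hr <- as.integer(format(series$timestamp, "%H", tz = "UTC"))
  lc <- log(pmax(series$count, 1))
  slope <- function(keep) {
    h <- hr[keep]; y <- lc[keep]
    o <- order(h); h <- h[o]; y <- y[o]
    if (method == "endpoints") {
      (y[length(y)] - y[1]) / (h[length(h)] - h[1])
    } else {
      stats::cov(h, y) / stats::var(h)
    }
  }
  days <- unique(day)
  if (length(days) < 2L) stop("need at least 2 days to fit a distribution")
  res <- t(vapply(seq_along(days), function(di) {
    d <- days[di]
    kg <- day == d & hr %in% growth_hours
    kd <- day == d & hr %in% decay_hours
    if (sum(kg) < 2L || sum(kd) < 2L)
      stop(sprintf("day %s lacks the hours needed for the fit",
                   format(d)))
    c(growth = slope(kg), decay = abs(slope(kd)))
  }, numeric(2)))
  out <- rate_distribution(colMeans(res), stats::cov(res))
  attr(out, "daily") <- data.frame(day = days, growth = res[, "growth"],
                                   decay = res[, "decay"])
  out
}

#' Sample a positive (growth, decay) rate pair
#'
#' Bivariate normal draw from the fitted distribution; draws with a
#' non-positive component are rejected and redrawn (at most `max_attempts`
#' times per requested pair).
#'
#' @param dist A [rate_distribution()].
#' @param n Number of pairs.
#' @param max_attempts Rejection budget per pair.
#' @return `n x 2` matrix with columns `growth`, `decay`, all entries
#'   strictly positive.
#' @export
resample_rates <- function(dist, n = 1, max_attempts = 100) {
  stopifnot(inherits(dist, "rate_distribution"))
  out <- matrix(NA_real_, n, 2,
                dimnames = list(NULL, c("growth", "decay")))
  degenerate <- all(dist$cov == 0)
  if (degenerate) {
    if (any(dist$mean <= 0))
      stop("could not draw a positive rate pair within the rejection ",
           "budget; the distribution is badly specified")
    out[, 1] <- dist$mean[1]
    out[, 2] <- dist$mean[2]
    return(out)
  }
  need <- seq_len(n)
  for (att in seq_len(max_attempts)) {
    cand <- matrix(MASS::mvrnorm(length(need), mu = dist$mean,
                                 Sigma = dist$cov), ncol = 2)
    ok <- cand[, 1] > 0 & cand[, 2] > 0
    out[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
    if (!length(need)) break
  }
  if (length(need))
    stop("could not draw a positive rate pair within the rejection ",
         "budget; the distribution is badly specified")
  out
}

#' Particle-filter weight update from one hourly observation
#'
#' Implements the recursion `w_k(i) proportional to w_{k-1}(i) *
#' p(z_k | forecast_k(i))`, where the observation error distribution is
#' normal for the logarithm of the counts with s.d. `obs_sd_log`. Both the
#' observation and the member forecasts are floored at 1 before logging.
#' The update is performed in log space and normalized by log-sum-exp, so
#' extreme outliers cannot underflow to an all-zero weight vector.
#'
#' @param weights Current normalized weights (non-negative, summing to 1).
#' @param z Observed count (scalar).
#' @param forecasts Member-predicted counts, one per weight.
#' @param obs_sd_log Log-space observation s.d. (default 0.05, the 5%
#'   measurement-error model).
#' @return Updated normalized weights.
#' @export
update_weights <- function(weights, z, forecasts, obs_sd_log = 0.05) {
  stopifnot(length(weights) == length(forecasts), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8)
    stop("`weights` must be normalized")
  lw <- ifelse(weights > 0, log(weights), -Inf)
  ll <- stats::dnorm(log(max(z, 1)), mean = log(pmax(forecasts, 1)),
                     sd = obs_sd_log, log = TRUE)
  lw <- lw + ll
  m <- max(lw)
  if (!is.finite(m)) stop("all weights vanished (every weight was zero)")
  w <- exp(lw - m)
  w / sum(w)
}

#' Systematic resampling by weight
#'
#' @param weights Normalized weights.
#' @param n Number of indices to draw (default `length(weights)`).
#' @return Integer member indices.
#' @export
systematic_resample <- function(weights, n = length(weights)) {
  u <- (stats::runif(1) + 0:(n - 1)) / n
  findInterval(u, cumsum(weights) + 1e-15 * seq_along(weights)) + 1L
}

#' Daily rate identification by resampling and likelihood weighting
#'
#' The hybrid scheme for volatile daily count profiles: at 00:00 of each
#' day every ensemble member draws fresh (growth, decay) rates from the
#' fitted [rate_distribution()] (akin to ensemble inflation), the ensemble
#' is run through a full 24 h forecast with no state update, and the hourly
#' observations multiply particle-filter weights that identify which
#' member -- and hence which rate pair -- best matches that day. At the end
#' of the day the configured update is applied (default: systematic
#' resampling of member states by the final weights) before the next day's
#' rate refresh; weights reset to uniform each midnight because days are
#' fitted independently.
#'
#' @param day_model Function `(rates, state, day_index)` returning
#'   `list(counts = <24 hourly counts>, state = <end-of-day state>)`. The
#'   `state` slot may be `NULL` for stateless profile models.
#' @param observations Hourly counts over whole days: a
#'   `footfall_series` with `24 * n_days` rows or a `n_days x 24` matrix.
#' @param dist A [rate_distribution()] to resample from.
#' @param config List: `n_members` (default 100), `obs_sd_log` (0.05),
#'   `top_k` (5), `resample_rates_daily` (TRUE), `initial_rates` (optional
#'   `n_members x 2` matrix used when not resampling, e.g. planted-truth
#'   experiments), `day_end` (`"resample"` or `"none"`), `init_states`
#'   (optional list of per-member states), `seed` (optional).
#' @return Object of class `daily_id_run`: per-day records with the member
#'   rates, the `n_members x 24` forecast and weight matrices, the top-`k`
#'   member indices per hour, and the hourly weight entropy.
#' @export
run_daily_identification <- function(day_model, observations, dist,
                                     config = list()) {
  stopifnot(inherits(dist, "rate_distribution"))
  obs <- if (inherits(observations, "footfall_series")) {
    if (nrow(observations) %% 24 != 0)
      stop("observations must cover whole days")
    matrix(observations$count, ncol = 24, byrow = TRUE)
  } else {
    as.matrix(observations)
  }
  if (ncol(obs) != 24) stop("expected 24 hourly observations per day")
  n_days <- nrow(obs)
  N <- config$n_members %||% 100L
  sd_log <- config$obs_sd_log %||% 0.05
  top_k <- config$top_k %||% 5L
  resample_daily <- config$resample_rates_daily %||% TRUE
  day_end <- config$day_end %||% "resample"
  if (!day_end %in% c("resample", "none"))
    stop("`day_end` must be \"resample\" or \"none\"")
  if (!is.null(config$seed)) set.seed(config$seed)
  states <- config$init_states %||% vector("list", N)
  rates <- config$initial_rates %||% resample_rates(dist, N)
  if (nrow(rates) != N) stop("`initial_rates` must have one row per member")

  days <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    if (resample_daily && d > 1L) rates <- resample_rates(dist, N)
    w <- rep(1 / N, N)
    fc <- matrix(0, N, 24)
    new_states <- states
    for (i in seq_len(N)) {
      r <- day_model(rates[i, ], states[[i]], d)
      if (length(r$counts) != 24)
        stop("`day_model` must return 24 hourly counts")
      fc[i, ] <- r$counts
      new_states[[i]] <- r$state
    }
    weight_hist <- matrix(0, N, 24)
    top <- matrix(NA_integer_, top_k, 24)
    entropy <- numeric(24)
    for (h in seq_len(24)) {
      w <- update_weights(w, obs[d, h], fc[, h], obs_sd_log = sd_log)
      weight_hist[, h] <- w
      top[, h] <- order(w, decreasing = TRUE)[seq_len(top_k)]
      pw <- w[w > 0]
      entropy[h] <- -sum(pw * log(pw))
    }
    days[[d]] <- list(day = d, rates = rates, forecasts = fc,
                      weights = weight_hist, top_members = top,
                      entropy = entropy, final_weights = w)
    states <- new_states
    if (day_end == "resample") {
      idx <- systematic_resample(w, N)
      states <- states[idx]
      rates <- rates[idx, , drop = FALSE]
    }
  }
  structure(list(days = days, n_members = N, config = config),
            class = "daily_id_run")
}
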