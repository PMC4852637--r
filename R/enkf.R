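#' Ensemble of model states
#'
#' Container for the ensemble Kalman filter: `N` model states of common
#' dimension `n`, stored as the rows of a matrix, together with component
#' names, a per-component flag saying whether that component is stored in
#' natural-log space, and the common model time.
#'
#' @param members `N x n` numeric matrix, one state per row.
#' @param names Component names (defaults to `colnames(members)`).
#' @param log_mask Logical vector, length `n`: `TRUE` for components stored
#'   in natural-log space. Recycled if length 1.
#' @param time Common model time of the members.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(members, names = colnames(members), log_mask = FALSE,
                     time = 0) {
  members <- as.matrix(members)
  attr(members, "clamped") <- NULL
  n <- ncol(members)
  if (is.null(names)) names <- paste0("x", seq_len(n))
  if (anyDuplicated(names)) stop("component names must be unique")
  if (length(names) != n) stop("`names` length must match state dimension")
  log_mask <- rep_len(as.logical(log_mask), n)
  if (any(!is.finite(members)))
    stop("ensemble members must be finite")
  colnames(members) <- names
  structure(list(members = members, names = names, log_mask = log_mask,
                 time = time, N = nrow(members)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: N = %d members, dimension %d, time %g\n",
              x$N, length(x$names), x$time))
  cat("components:", paste0(x$names, ifelse(x$log_mask, " (log)", "")), "\n")
  invisible(x)
}

#' Ensemble mean and covariance
#'
#' The arithmetic mean of the members and the sample covariance with the
#' `1/(N-1)` factor, i.e. `P = 1/(N-1) * sum_i e(i) e(i)^T` with
#' `e(i) = x(i) - mean`.
#'
#' @param ens An [ensemble()] (or bare member matrix).
#' @return List with `mean` (length-`n` vector) and `cov` (`n x n` matrix).
#' @export
ensemble_moments <- function(ens) {
  m <- if (inherits(ens, "ensemble")) ens$members else as.matrix(ens)
  if (nrow(m) < 2L) stop("at least 2 members are needed for a covariance")
  list(mean = colMeans(m), cov = stats::cov(m))
}

#' Linear-Gaussian observation model
#'
#' Observations `z = H x + nu`, `nu ~ N(0, R)`.
#'
#' @param H Forward matrix (`m x n`); a vector is treated as a single row.
#' @param R Observation covariance (`m x m`); a scalar is promoted.
#' @return Object of class `observation_model` with `H`, `R`, `m`.
#' @export
observation_model <- function(H, R) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1)
  m <- nrow(H)
  if (length(R) == 1L) R <- diag(as.numeric(R), m)
  R <- as.matrix(R)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10)))
    stop("`R` must be symmetric")
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    stop("`R` must be positive semi-definite")
  if (nrow(R) != m) stop("`R` dimension must match the rows of `H`")
  structure(list(H = H, R = R, m = m), class = "observation_model")
}

#' Kalman gain
#'
#' `K = P H^T (H P H^T + R)^{-1}`, computed by solving the linear system
#' `K (H P H^T + R) = P H^T` rather than by explicit inversion.
#'
#' @param P_f Forecast covariance (`n x n`).
#' @param obs An [observation_model()].
#' @return The `n x m` gain matrix.
#' @export
kalman_gain <- function(P_f, obs) {
  stopifnot(inherits(obs, "observation_model"))
  P_f <- as.matrix(P_f)
  H <- obs$H
  S <- H %*% P_f %*% t(H) + obs$R          # innovation covariance
  A <- H %*% P_f                           # = (P H^T)^T since P symmetric
  K <- tryCatch(t(solve(S, A)), error = function(e)
    stop("innovation covariance is singular; regularize R (add a small ",
         "positive diagonal)", call. = FALSE))
  K
}

#' Transform raw components into log space (and back)
#'
#' Components flagged in `log_mask` are replaced by their natural logarithm;
#' raw values below `floor` are clamped to `floor` first (counts of zero
#' occur in real data and `log(0)` is undefined). The number of clamped
#' entries is attached as attribute `"clamped"`. Unmasked components pass
#' through unchanged.
#'
#' @param values Numeric vector or matrix (components in columns).
#' @param log_mask Logical mask, recycled to the number of components.
#' @param floor Positivity floor applied before taking logs.
#' @return Transformed values, with attribute `"clamped"`.
#' @export
log_transform <- function(values, log_mask, floor = 1) {
  vec <- is.null(dim(values))
  m <- if (vec) matrix(values, nrow = 1) else as.matrix(values)
  log_mask <- rep_len(as.logical(log_mask), ncol(m))
  clamped <- 0L
  for (j in which(log_mask)) {
    low <- m[, j] < floor
    clamped <- clamped + sum(low)
    m[low, j] <- floor
    m[, j] <- log(m[, j])
  }
  out <- if (vec) stats::setNames(m[1, ], names(values)) else m
  attr(out, "clamped") <- clamped
  out
}

#' @rdname log_transform
#' @export
inverse_log_transform <- function(values, log_mask) {
  vec <- is.null(dim(values))
  m <- if (vec) matrix(values, nrow = 1) else as.matrix(values)
  log_mask <- rep_len(as.logical(log_mask), ncol(m))
  m[, log_mask] <- exp(m[, log_mask, drop = FALSE])
  out <- if (vec) m[1, ] else m
  if (vec) names(out) <- names(values)
  out
}

#' Append parameters to a model state (state augmentation)
#'
#' Sequential parameter estimation treats unknown parameters as extra state
#' components: they are carried by each ensemble member, evolve by
#' persistence during the forecast, and are updated only through their
#' ensemble covariance with the observed components.
#'
#' @param state Named numeric vector of model state components.
#' @param params Named numeric vector of parameters to append.
#' @return Named vector `c(state, params)`.
#' @export
augment_parameters <- function(state, params) {
  if (is.null(names(state)) || is.null(names(params)))
    stop("both `state` and `params` must be named")
  if (any(names(params) %in% names(state)))
    stop("parameter names clash with state names")
  c(state, params)
}

#' @rdname augment_parameters
#' @param x Augmented named vector.
#' @param state_names Names of the model-state components.
#' @return `project_back()`: list with `state` and `params`.
#' @export
project_back <- function(x, state_names) {
  if (!all(state_names %in% names(x)))
    stop("unknown component name(s): ",
         paste(setdiff(state_names, names(x)), collapse = ", "))
  list(state = x[state_names],
       params = x[setdiff(names(x), state_names)])
}

#' Forecast step: evolve every member with the model
#'
#' Each member is evolved independently from the ensemble time to `t_next`.
#' Members are handed to the model in raw (un-logged) units and re-logged on
#' return. The model contract is `function(state, t_start, t_end)` returning
#' a state of the same dimension; all stochasticity must come from R's
#' global random number stream so that a seeded run is reproducible.
#'
#' @param ens An [ensemble()].
#' @param model The evolution function.
#' @param t_next Forecast time, `> ens$time`.
#' @param log_floor Positivity floor used when re-logging (see
#'   [log_transform()]).
#' @return The forecast [ensemble()] at `t_next`.
#' @export
forecast_ensemble <- function(ens, model, t_next, log_floor = 1) {
  stopifnot(inherits(ens, "ensemble"))
  if (t_next <= ens$time)
    stop("`t_next` must be later than the ensemble time")
  raw <- inverse_log_transform(ens$members, ens$log_mask)
  out <- raw
  for (i in seq_len(ens$N)) {
    x <- raw[i, ]
    names(x) <- ens$names
    y <- model(x, ens$time, t_next)
    if (length(y) != length(x) || any(!is.finite(y)))
      stop(sprintf("model returned a non-finite or mis-sized state for member %d", i))
    out[i, ] <- y
  }
  fc <- log_transform(out, ens$log_mask, floor = log_floor)
  ensemble(fc, names = ens$names, log_mask = ens$log_mask, time = t_next)
}

#' Assimilate one observation (perturbed-observation analysis step)
#'
#' Each member receives its own "virtual observation" `z(i) = z + nu(i)`,
#' `nu(i) ~ N(0, R)`, and is shifted by the Kalman gain times its innovation:
#' `xhat(i) = xf(i) + K [z(i) - H xf(i)]`. Virtual observations give the
#' analysis ensemble the correct posterior spread.
#'
#' @param forecast Forecast [ensemble()].
#' @param z Observation vector (length `m`), on the same scale as the stored
#'   state (log scale for log-masked components).
#' @param obs An [observation_model()].
#' @param perturb If `FALSE`, virtual-observation noise is suppressed
#'   (useful for deterministic limits in tests).
#' @return An object of class `enkf_step` holding the forecast members,
#'   forecast mean/covariance, gain, virtual observations, analysis members,
#'   analysis mean/covariance, per-member forecast and analysis errors, and
#'   the step time.
#' @export
assimilate <- function(forecast, z, obs, perturb = TRUE) {
  stopifnot(inherits(forecast, "ensemble"),
            inherits(obs, "observation_model"))
  if (length(z) != obs$m) stop("observation dimension mismatch")
  mom <- ensemble_moments(forecast)
  K <- kalman_gain(mom$cov, obs)
  N <- forecast$N
  nu <- if (perturb) {
    MASS::mvrnorm(N, mu = rep(0, obs$m), Sigma = obs$R)
  } else {
    matrix(0, N, obs$m)
  }
  nu <- matrix(nu, nrow = N)
  virtual <- sweep(nu, 2L, as.numeric(z), "+")
  Xf <- forecast$members
  innov <- virtual - Xf %*% t(obs$H)
  Xa <- Xf + innov %*% t(K)
  amean <- colMeans(Xa)
  acov <- stats::cov(Xa)
  structure(list(
    time = forecast$time,
    forecast_members = Xf,
    forecast_mean = mom$mean,
    forecast_cov = mom$cov,
    gain = K,
    virtual_obs = virtual,
    analysis_members = Xa,
    analysis_mean = amean,
    analysis_cov = acov,
    forecast_errors = sweep(Xf, 2L, mom$mean),
    analysis_errors = sweep(Xa, 2L, amean)
  ), class = "enkf_step")
}

#' Run the ensemble Kalman filter over a series of observations
#'
#' Alternates forecast and analysis steps over strictly increasing
#' observation times. After each analysis, optional post-processing restores
#' model-required constraints before the next stochastic forecast:
#' components named in `config$round_components` are rounded half away from
#' zero and clamped at 0 (counts must be non-negative integers), and
#' components named in `config$clamp_floor` are clamped at the given
#' positive floors (guards against unphysical negative rates).
#'
#' @param model Evolution function (see [forecast_ensemble()]).
#' @param observations List with `times` (strictly increasing) and `z`
#'   (vector, or `length(times) x m` matrix). An empty set of times yields a
#'   pure forecast to `config$t_end`.
#' @param obs An [observation_model()].
#' @param init Initial [ensemble()].
#' @param config Optional list: `round_components` (character),
#'   `clamp_floor` (named numeric), `keep_members` (logical, default FALSE),
#'   `log_floor` (default 1), `t_end` (pure-forecast horizon).
#' @return Object of class `filter_run`: list with `steps` (one `enkf_step`
#'   per observation, reduced to means/covariances/gain unless
#'   `keep_members`), `times`, `final_ensemble` and the `config` snapshot.
#' @export
run_filter <- function(model, observations, obs, init, config = list()) {
  stopifnot(inherits(init, "ensemble"), inherits(obs, "observation_model"))
  times <- observations$times
  z <- observations$z
  keep <- isTRUE(config$keep_members)
  log_floor <- config$log_floor %||% 1
  if (length(times) == 0L) {
    horizon <- config$t_end
    if (is.null(horizon)) stop("no observations and no `t_end` horizon")
    ens <- forecast_ensemble(init, model, horizon, log_floor = log_floor)
    return(structure(list(steps = list(), times = numeric(0),
                          final_ensemble = ens, config = config),
                     class = "filter_run"))
  }
  if (any(diff(times) <= 0) || times[1] <= init$time)
    stop("observation times must be strictly increasing and after init time")
  z <- if (is.null(dim(z))) matrix(z, ncol = obs$m) else as.matrix(z)
  if (nrow(z) != length(times)) stop("observations/times length mismatch")

  ens <- init
  steps <- vector("list", length(times))
  for (k in seq_along(times)) {
    fc <- tryCatch(
      forecast_ensemble(ens, model, times[k], log_floor = log_floor),
      error = function(e) stop(sprintf("step %d (t=%g): %s", k, times[k],
                                       conditionMessage(e)), call. = FALSE))
    st <- assimilate(fc, z[k, ], obs)
    Xa <- st$analysis_members
    raw <- inverse_log_transform(Xa, ens$log_mask)
    colnames(raw) <- ens$names
    for (nm in config$round_components) {
      j <- match(nm, ens$names)
      raw[, j] <- pmax(0, sign(raw[, j]) * floor(abs(raw[, j]) + 0.5))
    }
    cf <- config$clamp_floor
    for (nm in names(cf)) {
      j <- match(nm, ens$names)
      raw[, j] <- pmax(cf[[nm]], raw[, j])
    }
    back <- log_transform(raw, ens$log_mask, floor = log_floor)
    ens <- ensemble(back, names = ens$names, log_mask = ens$log_mask,
                    time = times[k])
    if (!keep) {
      st$forecast_members <- NULL
      st$analysis_members <- NULL
      st$virtual_obs <- NULL
      st$forecast_errors <- NULL
      st$analysis_errors <- NULL
    }
    steps[[k]] <- st
  }
  structure(list(steps = steps, times = times, final_ensemble = ens,
                 config = config),
            class = "filter_run")
}

#' @export
print.filter_run <- function(x, ...) {
  cat(sprintf("EnKF run: %d analysis steps, final time %g, N = %d\n",
              length(x$steps), x$final_ensemble$time, x$final_ensemble$N))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
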