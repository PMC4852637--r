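#' Root-mean-square error
#'
#' @param predicted,reference Equal-length numeric vectors.
#' @return `sqrt(mean((predicted - reference)^2))`.
#' @export
rmse <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(predicted) < 1L)
    stop("`predicted` and `reference` must have equal positive length")
  sqrt(mean((predicted - reference)^2))
}

#' Benchmark forecasts for an hourly count series
#'
#' The four standard baselines for hourly counts on a weekday-contiguous
#' axis: the per-hour-of-day training mean (the same profile repeated every
#' day), persistence (the hour before, lag 1), the same hour the day
#' before (lag 24), and the same hour the week before (lag 120 = 5
#' weekdays x 24 h, because weekends have been removed). Every forecast at
#' time `k` uses only data strictly before `k`; test points without enough
#' history for a lag are excluded and counted.
#'
#' @param series A weekday-contiguous `footfall_series` (or numeric count
#'   vector).
#' @param n_test Number of trailing hours to score; everything before is
#'   training history.
#' @return Object of class `benchmark_report`: list with `rmse` (named
#'   vector), `forecasts` (named list of data.frames `index`, `predicted`,
#'   `observed`), `excluded` (points dropped per method) and `n_test`.
#' @export
benchmark_forecasts <- function(series, n_test) {
  x <- if (inherits(series, "footfall_series")) series$count else series
  n <- length(x)
  if (n_test < 1L || n_test >= n)
    stop("`n_test` must leave at least one training point")
  test_idx <- (n - n_test + 1L):n
  train_idx <- seq_len(n - n_test)
  hour <- (seq_len(n) - 1L) %% 24L
  hmean <- tapply(x[train_idx], hour[train_idx], mean)
  lags <- c("hourly-mean" = NA, "persistence" = 1,
            "day-before" = 24, "week-before" = 120)
  forecasts <- list()
  scores <- numeric(0)
  excluded <- integer(0)
  for (m in names(lags)) {
    if (m == "hourly-mean") {
      pred <- as.numeric(hmean[as.character(hour[test_idx])])
      keep <- !is.na(pred)
    } else {
      src <- test_idx - lags[[m]]
      keep <- src >= 1L
      pred <- ifelse(keep, x[pmax(src, 1L)], NA_real_)
    }
    forecasts[[m]] <- data.frame(index = test_idx[keep],
                                 predicted = pred[keep],
                                 observed = x[test_idx][keep])
    scores[m] <- rmse(pred[keep], x[test_idx][keep])
    excluded[m] <- sum(!keep)
  }
  structure(list(rmse = scores, forecasts = forecasts, excluded = excluded,
                 n_test = n_test),
            class = "benchmark_report")
}

#' Reference RMSE scores on the Briggate footfall data
#'
#' Documented reference values obtained on the real Leeds city-centre
#' footfall data (six-week test window, weekdays): they require the
#' external dataset and are retained here for comparison only, not as test
#' assertions.
#'
#' @return Named vector of RMSE scores.
#' @export
reference_rmse_leeds <- function() {
  c("enkf-N10" = 1141, "enkf-N100" = 549.2, "enkf-N1000" = 457.3,
    "hourly-mean" = 565.2, "persistence" = 519.4, "day-before" = 435.9,
    "week-before" = 330.1)
}

#' Evolution model for the box process (known parameters)
#'
#' Adapter turning the immigration-death Gillespie simulator into the
#' `function(state, t0, t1)` contract of [forecast_ensemble()]. The single
#' state component `x` is rounded half away from zero and clamped at 0
#' before the jump process restarts from it.
#'
#' @param params A [box_params()].
#' @return Evolution function for a 1-component state named `x`.
#' @export
box_evolution_model <- function(params) {
  stopifnot(inherits(params, "box_params"))
  function(x, t0, t1) {
    x0 <- max(0, round(x[["x"]]))
    out <- box_gillespie_cpp(params$alpha, params$beta, as.integer(x0),
                             t1 - t0, Inf)
    c(x = as.numeric(out))
  }
}

#' Evolution model for the box process with augmented parameters
#'
#' State vector `(x, alpha, beta)`: the count evolves by the member's own
#' rates, the rates themselves evolve by persistence. Rates are clamped at
#' a small positive floor before simulation so that an aggressive analysis
#' update cannot produce a negative-rate jump process.
#'
#' @param rate_floor Positive floor applied to `alpha` and `beta`.
#' @return Evolution function for the augmented state.
#' @export
box_augmented_model <- function(rate_floor = 1e-6) {
  function(x, t0, t1) {
    a <- max(x[["alpha"]], rate_floor)
    b <- max(x[["beta"]], rate_floor)
    x0 <- max(0, round(x[["x"]]))
    out <- box_gillespie_cpp(a, b, as.integer(x0), t1 - t0, Inf)
    c(x = as.numeric(out), alpha = a, beta = b)
  }
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Rounded-normal initial counts
#'
#' Normal draws rounded half away from zero and clamped at 0: counts must
#' be non-negative integers.
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters.
#' @return Integer-valued draws.
#' @export
rounded_normal <- function(n, mean, sd) {
  pmax(0, round_half_away(stats::rnorm(n, mean, sd)))
}

#' Synthetic-truth state-estimation experiment for the box model
#'
#' Replicates the box-model state-estimation workflow: simulate one
#' Gillespie trajectory as ground truth, observe it with additive Gaussian
#' noise, run the EnKF with the true rates, and score forecast, analysis,
#' observation and constant-steady-state RMSEs over the observation steps
#' (the initial time is not scored). Each seed produces an independent
#' replicate; the pooled report averages per-seed RMSEs.
#'
#' @param config List overriding the defaults `alpha = 52.52`,
#'   `beta = 0.2580`, `x0 = 200`, `n_steps = 100`, `R = 16`, `N = 100`,
#'   `init_mean = 200`, `init_var = 200`.
#' @param seeds Integer vector of seeds, one replicate each.
#' @return Object of class `score_report`: `per_seed` data.frame,
#'   `pooled` named means, `frac_analysis_beats_obs`, and the config.
#' @export
run_box_state_estimation <- function(config = list(), seeds = 1:30) {
  cfg <- utils::modifyList(list(alpha = 52.52, beta = 0.2580, x0 = 200,
                                n_steps = 100, R = 16, N = 100,
                                init_mean = 200, init_var = 200), config)
  params <- box_params(cfg$alpha, cfg$beta)
  g <- box_gamma(params)
  obs_model <- observation_model(H = 1, R = cfg$R)
  model <- box_evolution_model(params)
  per_seed <- lapply(seeds, function(s) {
    set.seed(s)
    times <- 0:cfg$n_steps
    truth <- simulate_box(params, cfg$x0, times)$counts
    z <- truth[-1] + stats::rnorm(cfg$n_steps, 0, sqrt(cfg$R))
    init <- ensemble(matrix(rounded_normal(cfg$N, cfg$init_mean,
                                           sqrt(cfg$init_var)), ncol = 1),
                     names = "x", time = 0)
    run <- run_filter(model, list(times = 1:cfg$n_steps, z = z), obs_model,
                      init, config = list(round_components = "x"))
    fmean <- vapply(run$steps, function(st) st$forecast_mean[["x"]],
                    numeric(1))
    amean <- vapply(run$steps, function(st) st$analysis_mean[["x"]],
                    numeric(1))
    ref <- truth[-1]
    data.frame(seed = s,
               rmse_forecast = rmse(fmean, ref),
               rmse_analysis = rmse(amean, ref),
               rmse_observation = rmse(z, ref),
               rmse_steady = rmse(rep(g, cfg$n_steps), ref))
  })
  per_seed <- do.call(rbind, per_seed)
  structure(list(
    per_seed = per_seed,
    pooled = colMeans(per_seed[, -1]),
    frac_analysis_beats_obs =
      mean(per_seed$rmse_analysis < per_seed$rmse_observation),
    config = cfg, seeds = seeds),
    class = "score_report")
}

#' Sequential parameter estimation experiment for the box model
#'
#' Same synthetic truth as [run_box_state_estimation()], but the rates are
#' treated as unknown: each member carries its own `(alpha, beta)` drawn
#' from the priors `N(50, 25)` and `N(0.25, 1e-4)`, appended to the state
#' vector and updated only through their ensemble covariance with the
#' observed count. Reports the state RMSEs plus the final parameter means
#' and their ratio `alpha / beta` (the stationary mean the data actually
#' constrain).
#'
#' @param config As in [run_box_state_estimation()], plus
#'   `prior_alpha = c(50, 25)` and `prior_beta = c(0.25, 1e-4)`
#'   (mean, variance) and `rate_floor = 1e-6`.
#' @param seeds Integer seeds.
#' @return A `score_report`; `per_seed` additionally holds
#'   `alpha_hat`, `beta_hat`, `ratio` (analysis means at the final step)
#'   and the pooled slot holds `median_ratio`.
#' @export
run_box_parameter_estimation <- function(config = list(), seeds = 1:30) {
  cfg <- utils::modifyList(list(alpha = 52.52, beta = 0.2580, x0 = 200,
                                n_steps = 100, R = 16, N = 100,
                                init_mean = 200, init_var = 200,
                                prior_alpha = c(50, 25),
                                prior_beta = c(0.25, 1e-4),
                                rate_floor = 1e-6), config)
  params <- box_params(cfg$alpha, cfg$beta)
  obs_model <- observation_model(H = c(1, 0, 0), R = cfg$R)
  model <- box_augmented_model(rate_floor = cfg$rate_floor)
  per_seed <- lapply(seeds, function(s) {
    set.seed(s)
    times <- 0:cfg$n_steps
    truth <- simulate_box(params, cfg$x0, times)$counts
    z <- truth[-1] + stats::rnorm(cfg$n_steps, 0, sqrt(cfg$R))
    members <- cbind(
      x = rounded_normal(cfg$N, cfg$init_mean, sqrt(cfg$init_var)),
      alpha = stats::rnorm(cfg$N, cfg$prior_alpha[1],
                           sqrt(cfg$prior_alpha[2])),
      beta = stats::rnorm(cfg$N, cfg$prior_beta[1],
                          sqrt(cfg$prior_beta[2])))
    init <- ensemble(members, time = 0)
    run <- run_filter(model, list(times = 1:cfg$n_steps, z = z), obs_model,
                      init,
                      config = list(round_components = "x",
                                    clamp_floor = c(alpha = cfg$rate_floor,
                                                    beta = cfg$rate_floor)))
    fmean <- vapply(run$steps, function(st) st$forecast_mean[["x"]],
                    numeric(1))
    amean <- vapply(run$steps, function(st) st$analysis_mean[["x"]],
                    numeric(1))
    fin <- run$steps[[length(run$steps)]]
    ref <- truth[-1]
    data.frame(seed = s,
               rmse_forecast = rmse(fmean, ref),
               rmse_analysis = rmse(amean, ref),
               rmse_observation = rmse(z, ref),
               alpha_hat = fin$analysis_mean[["alpha"]],
               beta_hat = fin$analysis_mean[["beta"]],
               ratio = fin$analysis_mean[["alpha"]] /
                 fin$analysis_mean[["beta"]])
  })
  per_seed <- do.call(rbind, per_seed)
  pooled <- colMeans(per_seed[, -1])
  pooled["median_ratio"] <- stats::median(per_seed$ratio)
  structure(list(
    per_seed = per_seed,
    pooled = pooled,
    frac_analysis_beats_obs =
      mean(per_seed$rmse_analysis < per_seed$rmse_observation),
    config = cfg, seeds = seeds),
    class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("Experiment over", length(x$seeds), "seed(s); pooled scores:\n")
  print(round(x$pooled, 4))
  cat(sprintf("analysis beats observation in %.0f%% of seeds\n",
              100 * x$frac_analysis_beats_obs))
  invisible(x)
}

#' Default WHIRS parameters for the synthetic footfall experiments
#'
#' A parameter set of our own choosing (the scale of a mid-sized high
#' street, not fitted to any dataset): an agent pool of 2000 with 400
#' workers; a weak baseline attraction (1 arrival event/hour) so that the
#' morning growth of in-town counts is driven by the social-amplification
#' term at roughly exponential rate `alpha S b / N - beta` of about half a
#' unit per hour (`b` the mean batch size of about 3); mean shopper visits
#' of `1/beta` of about 3 h; and commuter base rates sized to move most of
#' the 400 workers in over the morning window.
#'
#' @param N Agent pool size.
#' @return A [whirs_params()].
#' @export
whirs_default_params <- function(N = 2000) {
  whirs_params(N = N, N_w = round(0.2 * N),
               epsilon = 1, alpha = 0.45, beta = 0.35,
               gamma_minus = 50, delta_minus = 0.25,
               gamma_plus = 20, delta_plus = 0.05,
               mu = 1, sigma = 0.5)
}

#' EnKF train/test experiment on WHIRS-generated footfall
#'
#' Self-consistency experiment: hourly counts are generated by the WHIRS
#' model itself (with known parameters) over a training and a test window,
#' observed through the 5% multiplicative lognormal error model, and the
#' EnKF -- with the full log-space augmented state vector -- is trained on
#' the first window and evaluated on the second, re-using the final
#' training ensemble as the test initial condition. The one-step-ahead
#' forecast of the camera count is scored against the observed data and
#' against the four benchmark forecasts.
#'
#' @param config List overriding: `truth_params`
#'   ([whirs_default_params()]), `n_train_days`, `n_test_days` (10 each),
#'   `N` ensemble size (100), `obs_sd_log` (0.05), `prior_spread` (log-sd
#'   of the lognormal parameter priors around the truth, 0.3),
#'   `tie_gamma` (FALSE).
#' @param seed Integer seed.
#' @return List with `rmse_forecast` (EnKF test-window score),
#'   `benchmarks` (a `benchmark_report` on the same series), `run_train`,
#'   `run_test`, and the truth/observed series.
#' @export
run_whirs_enkf <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(
    list(truth_params = whirs_default_params(),
         n_train_days = 10, n_test_days = 10, N = 100,
         obs_sd_log = 0.05, prior_spread = 0.3, tie_gamma = FALSE),
    config)
  set.seed(seed)
  p <- cfg$truth_params
  n_days <- cfg$n_train_days + cfg$n_test_days
  n_shop <- p$N - p$N_w
  init <- whirs_state(S = n_shop, H_home = p$N_w)
  sim <- simulate_whirs(p, init, t_end = 24 * n_days)
  truth <- sim$hourly$count
  spec <- noise_spec("multiplicative-lognormal", cfg$obs_sd_log)
  observed <- apply_noise(truth, spec)

  mask <- whirs_log_mask(tie_gamma = cfg$tie_gamma)
  nm <- names(mask)
  model <- whirs_evolution_model(windows = p$windows,
                                 tie_gamma = cfg$tie_gamma)
  # lognormal priors centred on the truth with relative spread prior_spread
  truth_vec <- whirs_pack(init, p, tie_gamma = cfg$tie_gamma)
  members <- matrix(0, cfg$N, length(nm), dimnames = list(NULL, nm))
  for (j in seq_along(nm)) {
    v <- truth_vec[[j]]
    members[, j] <- if (nm[j] == "mu") {
      stats::rnorm(cfg$N, v, cfg$prior_spread)
    } else if (nm[j] %in% c("S", "I", "H", "C", "N", "N_w")) {
      round(pmax(v, 1) * exp(stats::rnorm(cfg$N, 0, cfg$prior_spread / 3)))
    } else {
      pmax(v, 1e-3) * exp(stats::rnorm(cfg$N, 0, cfg$prior_spread))
    }
  }
  members[, "N_w"] <- pmin(members[, "N_w"], members[, "N"])
  init_ens <- ensemble(log_transform(members, mask),
                       names = nm, log_mask = mask, time = 0)
  H <- matrix(as.numeric(nm == "C"), nrow = 1)
  obs_model <- observation_model(H = H, R = cfg$obs_sd_log^2)
  n_train_h <- 24 * cfg$n_train_days
  train_z <- log(pmax(observed[seq_len(n_train_h)], 1))
  run_train <- run_filter(model, list(times = seq_len(n_train_h),
                                      z = train_z),
                          obs_model, init_ens)
  test_hours <- (n_train_h + 1):(24 * n_days)
  test_z <- log(pmax(observed[test_hours], 1))
  run_test <- run_filter(model, list(times = test_hours, z = test_z),
                         obs_model, run_train$final_ensemble)
  fmean <- vapply(run_test$steps, function(st)
    exp(st$forecast_mean[["C"]]), numeric(1))
  score <- rmse(fmean, observed[test_hours])
  bench <- benchmark_forecasts(observed, n_test = length(test_hours))
  list(rmse_forecast = score, benchmarks = bench,
       run_train = run_train, run_test = run_test,
       truth = truth, observed = observed, config = cfg, seed = seed)
}
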