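#' WHIRS model parameters
#'
#' The WHIRS model splits a fixed pool of `N` agents into `N_w` workers
#' (at **H**ome or at **W**ork) and `N - N_w` shoppers (**S**usceptible,
#' **I**n town, or **R**eturned home). Within the shopper-arrival window,
#' susceptible shoppers go into town at rate `epsilon + alpha S (I+W)/N`
#' (a constant attraction plus a rich-get-richer social term); shoppers in
#' town leave at per-capita rate `beta`; workers commute in at rate
#' `gamma_minus + delta_minus W` during the morning window and out at rate
#' `gamma_plus + delta_plus W` during the evening window. Shopper moves
#' carry a batch of agents whose size is a rounded lognormal (log-mean `mu`,
#' log-s.d. `sigma`), modelling correlated arrivals by shared transport.
#' A virtual camera accumulates every agent movement into an hourly count.
#'
#' @param N Total number of agents.
#' @param N_w Number of workers, `0 <= N_w <= N`.
#' @param epsilon Baseline shopper arrival rate (events/hour).
#' @param alpha Social-amplification rate (events/hour).
#' @param beta Per-capita shopper departure rate (/hour).
#' @param gamma_minus,delta_minus Worker to-work base and amplification
#'   rates (/hour).
#' @param gamma_plus,delta_plus Worker to-home base and amplification rates
#'   (/hour).
#' @param mu,sigma Log-mean and log-s.d. of the shopper batch-size
#'   distribution.
#' @param windows List of half-open `[start, end)` clock-hour windows:
#'   `shopper` (default 09:00-18:00), `worker_in` (06:00-10:00),
#'   `worker_out` (14:00-23:00).
#' @return Object of class `whirs_params`.
#' @export
whirs_params <- function(N, N_w, epsilon, alpha, beta,
                         gamma_minus, delta_minus,
                         gamma_plus, delta_plus,
                         mu, sigma,
                         windows = list(shopper = c(9, 18),
                                        worker_in = c(6, 10),
                                        worker_out = c(14, 23))) {
  rates <- c(epsilon = epsilon, alpha = alpha, beta = beta,
             gamma_minus = gamma_minus, delta_minus = delta_minus,
             gamma_plus = gamma_plus, delta_plus = delta_plus)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (sigma < 0) stop("`sigma` must be non-negative")
  if (N_w < 0 || N_w > N) stop("`N_w` must satisfy 0 <= N_w <= N")
  stopifnot(is.list(windows),
            all(c("shopper", "worker_in", "worker_out") %in% names(windows)))
  structure(list(N = N, N_w = N_w, epsilon = epsilon, alpha = alpha,
                 beta = beta, gamma_minus = gamma_minus,
                 delta_minus = delta_minus, gamma_plus = gamma_plus,
                 delta_plus = delta_plus, mu = mu, sigma = sigma,
                 windows = windows),
            class = "whirs_params")
}

#' WHIRS model state
#'
#' @param S,I,R Susceptible / in-town / returned shoppers.
#' @param H_home,W Workers at home / at work.
#' @param C Camera count accumulated in the current hour.
#' @param t Model clock in hours (weekday-continuous: the axis holds only
#'   weekdays, so 23:00 Friday is adjacent to 00:00 Monday).
#' @return Object of class `whirs_state`.
#' @export
whirs_state <- function(S, I = 0, R = 0, H_home = 0, W = 0, C = 0, t = 0) {
  v <- c(S = S, I = I, R = R, H_home = H_home, W = W, C = C)
  if (any(v < 0) || any(v != round(v)))
    stop("all compartments must be non-negative integers")
  structure(list(S = S, I = I, R = R, H_home = H_home, W = W, C = C, t = t),
            class = "whirs_state")
}

hour_of_day <- function(t) floor(t + 1e-9) %% 24

in_window <- function(t, win) {
  h <- hour_of_day(t)
  h >= win[1] & h < win[2]
}

#' Shopper arrival rate
#'
#' `epsilon + alpha S (I+W)/N` while `S > 0` and the clock hour lies in the
#' shopper window; 0 otherwise.
#'
#' @param state A [whirs_state()].
#' @param params A [whirs_params()].
#' @return Rate in events/hour.
#' @export
shopper_arrival_rate <- function(state, params) {
  if (state$S <= 0 || !in_window(state$t, params$windows$shopper)) return(0)
  params$epsilon + params$alpha * state$S * (state$I + state$W) / params$N
}

#' Worker commuting rates
#'
#' To-work rate `gamma_minus + delta_minus W` during the morning window
#' while any worker is at home; to-home rate `gamma_plus + delta_plus W`
#' during the evening window while any worker is at work; 0 otherwise.
#'
#' @inheritParams shopper_arrival_rate
#' @return Named vector `c(to_work, to_home)` in events/hour.
#' @export
worker_rates <- function(state, params) {
  to_work <- if (state$H_home > 0 &&
                 in_window(state$t, params$windows$worker_in)) {
    params$gamma_minus + params$delta_minus * state$W
  } else 0
  to_home <- if (state$W > 0 &&
                 in_window(state$t, params$windows$worker_out)) {
    params$gamma_plus + params$delta_plus * state$W
  } else 0
  c(to_work = to_work, to_home = to_home)
}

#' Draw a shopper batch size
#'
#' Samples `exp(Normal(mu, sigma^2))`, rounds half away from zero, then
#' clamps into `[1, cap]` (a batch cannot exceed the agents available).
#'
#' @param mu,sigma Log-mean and log-s.d.
#' @param cap Maximum batch size, `>= 1`.
#' @param n Number of draws.
#' @return Integer-valued draws in `[1, cap]`.
#' @export
draw_batch_size <- function(mu, sigma, cap, n = 1) {
  if (any(cap < 1)) stop("`cap` must be at least 1")
  raw <- exp(stats::rnorm(n, mu, sigma))
  pmin(pmax(floor(raw + 0.5), 1), cap)
}

#' Simulate the WHIRS model (Gillespie algorithm)
#'
#' Exact event-driven simulation with piecewise-constant-in-time rates: a
#' candidate waiting time that would cross the next scheduled boundary (all
#' boundaries fall on integer hours) is discarded, the clock advances to the
#' boundary, scheduled actions fire (hourly camera record and reset;
#' midnight return of all `R` shoppers to `S`), and the waiting time is
#' redrawn -- valid by memorylessness of the exponential. Shopper arrival
#' moves a batch `S -> I`, shopper departure a batch `I -> R`, both adding
#' the batch size to the camera count `C`; worker moves are single-agent and
#' add 1 to `C` (the camera is direction-blind).
#'
#' @param params A [whirs_params()].
#' @param init A [whirs_state()] whose compartments satisfy
#'   `S + I + R = N - N_w` and `H_home + W = N_w`.
#' @param t_end End time in hours, `> init$t` (hourly counts are recorded
#'   for whole hours).
#' @param max_events Stop generating events after this many (the clock still
#'   advances to `t_end` with the state frozen).
#' @param record_events If `TRUE`, return the full event log
#'   (`time`, `type`, `size`; types 1..4 = shopper arrival, shopper
#'   departure, worker to work, worker to home).
#' @param seed Optional integer seed.
#' @return List with `hourly` (data.frame `hour_start`, `count`), `states`
#'   (matrix of compartments just after each hour boundary), `final_state`,
#'   `n_events`, and `events` (matrix or `NULL`).
#' @export
simulate_whirs <- function(params, init, t_end, max_events = Inf,
                           record_events = FALSE, seed = NULL) {
  stopifnot(inherits(params, "whirs_params"), inherits(init, "whirs_state"))
  if (t_end <= init$t) stop("`t_end` must be later than `init$t`")
  if (init$S + init$I + init$R != params$N - params$N_w)
    stop("shopper conservation violated: S + I + R must equal N - N_w")
  if (init$H_home + init$W != params$N_w)
    stop("worker conservation violated: H_home + W must equal N_w")
  if (!is.null(seed)) set.seed(seed)
  res <- whirs_gillespie_cpp(
    c(init$S, init$I, init$R, init$H_home, init$W, init$C),
    init$t, t_end,
    params$N, params$N_w, params$epsilon, params$alpha, params$beta,
    params$gamma_minus, params$delta_minus,
    params$gamma_plus, params$delta_plus,
    params$mu, params$sigma,
    params$windows$shopper, params$windows$worker_in,
    params$windows$worker_out,
    max_events, record_events)
  hourly <- data.frame(hour_start = res$hour_start,
                       count = res$hourly_counts)
  fs <- res$final_state
  final <- whirs_state(S = fs[["S"]], I = fs[["I"]], R = fs[["R"]],
                       H_home = fs[["H_home"]], W = fs[["W"]],
                       C = fs[["C"]], t = res$final_time)
  list(hourly = hourly, states = res$hourly_state, final_state = final,
       n_events = res$n_events, event_budget_hit = res$event_budget_hit,
       events = res$events)
}

#' Pack a WHIRS state and parameters into an EnKF state vector
#'
#' The filter state vector is `(S, I, H, C, N, N_w, alpha, beta, epsilon,
#' gamma..., delta_plus, delta_minus, sigma, mu)`. With `tie_gamma = TRUE` a
#' single `gamma` stands for both commuting base rates; otherwise
#' `gamma_minus` and `gamma_plus` are packed separately. The derived
#' compartments are recovered on unpacking from the conservation identities
#' `R = (N - N_w) - S - I` and `W = N_w - H`.
#'
#' @param state A [whirs_state()].
#' @param params A [whirs_params()].
#' @param tie_gamma Use a single shared `gamma` component?
#' @return Named numeric vector.
#' @export
whirs_pack <- function(state, params, tie_gamma = FALSE) {
  gpart <- if (tie_gamma) {
    c(gamma = params$gamma_minus)
  } else {
    c(gamma_minus = params$gamma_minus, gamma_plus = params$gamma_plus)
  }
  c(S = state$S, I = state$I, H = state$H_home, C = state$C,
    N = params$N, N_w = params$N_w,
    alpha = params$alpha, beta = params$beta, epsilon = params$epsilon,
    gpart,
    delta_plus = params$delta_plus, delta_minus = params$delta_minus,
    sigma = params$sigma, mu = params$mu)
}

#' @rdname whirs_pack
#' @param x Packed state vector.
#' @param windows Rate windows to restore into the parameters (packing does
#'   not carry them).
#' @param t Model time to stamp on the state.
#' @return `whirs_unpack()`: list with `state` ([whirs_state()]), `params`
#'   ([whirs_params()]) and `n_clamped` (count of conservation repairs).
#' @export
whirs_unpack <- function(x, windows = list(shopper = c(9, 18),
                                           worker_in = c(6, 10),
                                           worker_out = c(14, 23)),
                         t = 0, tie_gamma = FALSE) {
  need <- c("S", "I", "H", "C", "N", "N_w", "alpha", "beta", "epsilon",
            if (tie_gamma) "gamma" else c("gamma_minus", "gamma_plus"),
            "delta_plus", "delta_minus", "sigma", "mu")
  if (!all(need %in% names(x)))
    stop("missing component(s): ", paste(setdiff(need, names(x)),
                                         collapse = ", "))
  rnd <- function(v) pmax(0, floor(abs(v) + 0.5) * sign(v))
  N <- max(rnd(x[["N"]]), 1)
  N_w <- min(max(rnd(x[["N_w"]]), 0), N)
  S <- rnd(x[["S"]]); I <- rnd(x[["I"]]); H <- rnd(x[["H"]])
  C <- rnd(x[["C"]])
  n_clamped <- 0L
  # restore shopper conservation: R is derived, S absorbs any deficit
  n_shop <- N - N_w
  if (S + I > n_shop) {
    n_clamped <- n_clamped + 1L
    S <- max(n_shop - I, 0)
    I <- min(I, n_shop)
  }
  R <- n_shop - S - I
  if (H > N_w) {
    n_clamped <- n_clamped + 1L
    H <- N_w
  }
  W <- N_w - H
  gm <- if (tie_gamma) x[["gamma"]] else x[["gamma_minus"]]
  gp <- if (tie_gamma) x[["gamma"]] else x[["gamma_plus"]]
  params <- whirs_params(
    N = N, N_w = N_w, epsilon = max(x[["epsilon"]], 0),
    alpha = max(x[["alpha"]], 0), beta = max(x[["beta"]], 0),
    gamma_minus = max(gm, 0), delta_minus = max(x[["delta_minus"]], 0),
    gamma_plus = max(gp, 0), delta_plus = max(x[["delta_plus"]], 0),
    mu = x[["mu"]], sigma = max(x[["sigma"]], 0), windows = windows)
  list(state = whirs_state(S = S, I = I, R = R, H_home = H, W = W, C = C,
                           t = t),
       params = params, n_clamped = n_clamped)
}

#' Log mask for the packed WHIRS state vector
#'
#' All components are stored in natural-log space except `mu`, which can be
#' negative.
#'
#' @param tie_gamma Single shared `gamma`? (Changes the vector length.)
#' @return Named logical vector.
#' @export
whirs_log_mask <- function(tie_gamma = FALSE) {
  nm <- names(whirs_pack(whirs_state(S = 1), whirs_params(
    N = 1, N_w = 0, epsilon = 0, alpha = 0, beta = 0, gamma_minus = 0,
    delta_minus = 0, gamma_plus = 0, delta_plus = 0, mu = 0, sigma = 0),
    tie_gamma = tie_gamma))
  stats::setNames(nm != "mu", nm)
}

#' Evolution-model adapter for the EnKF
#'
#' Builds the interface function that lets [run_filter()] drive the WHIRS
#' simulator: it unpacks an EnKF state vector (rounding counts and clamping
#' rates to valid values, restoring the derived compartments from
#' conservation), runs [simulate_whirs()] from `t0` to `t1`, and repacks
#' with `C` set to the camera count accumulated over the hour ending at
#' `t1`.
#'
#' @param windows Rate windows used by every member.
#' @param tie_gamma Single shared `gamma` component?
#' @return A `function(x, t0, t1)` suitable for [forecast_ensemble()].
#' @export
whirs_evolution_model <- function(windows = list(shopper = c(9, 18),
                                                 worker_in = c(6, 10),
                                                 worker_out = c(14, 23)),
                                  tie_gamma = FALSE) {
  function(x, t0, t1) {
    up <- whirs_unpack(x, windows = windows, t = t0, tie_gamma = tie_gamma)
    sim <- simulate_whirs(up$params, up$state, t_end = t1)
    fs <- sim$final_state
    nh <- nrow(sim$hourly)
    c_last <- if (nh >= 1) sim$hourly$count[nh] else fs$C
    st <- whirs_state(S = fs$S, I = fs$I, R = fs$R, H_home = fs$H_home,
                      W = fs$W, C = c_last, t = t1)
    whirs_pack(st, up$params, tie_gamma = tie_gamma)
  }
}
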