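shop_params <- function(...) {
  args <- utils::modifyList(
    list(N = 1000, N_w = 200, epsilon = 2, alpha = 0.5, beta = 0.4,
         gamma_minus = 30, delta_minus = 0.1, gamma_plus = 20,
         delta_plus = 0.05, mu = 1, sigma = 0.5),
    list(...))
  do.call(whirs_params, args)
}

test_that("rate laws respect the time-of-day windows and availability", {
  p <- shop_params()
  st <- function(S = 500, I = 0, R = 0, H = 200, W = 0, t = 0) {
    whirs_state(S = S, I = I, R = R, H_home = H, W = W, t = t)
  }
  # shoppers: zero outside 09:00-18:00, zero when S exhausted
  expect_equal(shopper_arrival_rate(st(t = 3), p), 0)
  expect_equal(shopper_arrival_rate(st(S = 0, I = 500, t = 10), p), 0)
  # amplification vanishes with nobody in town: exactly epsilon
  expect_equal(shopper_arrival_rate(st(t = 10), p), p$epsilon)
  # full law
  s1 <- st(S = 400, I = 60, W = 40, H = 160, t = 11)
  expect_equal(shopper_arrival_rate(s1, p),
               p$epsilon + p$alpha * 400 * (60 + 40) / p$N)

  # workers: both rates zero at midday
  expect_equal(unname(worker_rates(st(t = 12), p)), c(0, 0))
  # morning window: gamma_minus + delta_minus * W
  p2 <- shop_params(gamma_minus = 2, delta_minus = 0.1)
  expect_equal(worker_rates(st(W = 10, H = 190, t = 7), p2)[["to_work"]], 3)
  # nobody at work: no to-home rate even inside the window
  expect_equal(worker_rates(st(W = 0, H = 200, t = 15), p)[["to_home"]], 0)
})

test_that("batch sizes are integer, clamped, and mean-consistent", {
  set.seed(1)
  expect_equal(draw_batch_size(log(3), 0, 10, n = 20), rep(3, 20))
  d <- draw_batch_size(1, 0.5, 4, n = 1000)
  expect_true(all(d >= 1 & d <= 4))
  expect_true(all(d == round(d)))
  # Monte-Carlo mean vs direct mass-summation oracle, within 1%
  mc <- mean(draw_batch_size(1, 0.5, Inf, n = 1e5))
  expect_lt(abs(mc / rounded_lognormal_mean(1, 0.5) - 1), 0.01)
  expect_error(draw_batch_size(1, 0.5, 0), "at least 1")
})

test_that("a rateless model generates no events and no counts", {
  p <- shop_params(epsilon = 0, alpha = 0, beta = 0, N_w = 0,
                   gamma_minus = 0, delta_minus = 0, gamma_plus = 0,
                   delta_plus = 0)
  init <- whirs_state(S = 1000)
  sim <- simulate_whirs(p, init, t_end = 48, seed = 2)
  expect_equal(sim$n_events, 0)
  expect_true(all(sim$hourly$count == 0))
  expect_equal(sim$final_state$S, 1000)
})

test_that("conservation holds at every recorded state and after midnight", {
  p <- shop_params()
  init <- whirs_state(S = p$N - p$N_w, H_home = p$N_w)
  sim <- simulate_whirs(p, init, t_end = 72, seed = 3)
  st <- sim$states
  expect_true(all(st[, "S"] + st[, "I"] + st[, "R"] == p$N - p$N_w))
  expect_true(all(st[, "H_home"] + st[, "W"] == p$N_w))
  expect_true(all(st >= 0))
  # states recorded just after a midnight boundary have R swept into S
  midnight <- which(sim$hourly$hour_start %% 24 == 23)
  expect_true(length(midnight) >= 2)
  expect_true(all(st[midnight, "R"] == 0))
  # and some shoppers did return before midnight on at least one day
  expect_gt(max(st[, "R"]), 0)
})

test_that("the camera audit is exact: hourly C = sum of event sizes", {
  p <- shop_params()
  init <- whirs_state(S = p$N - p$N_w, H_home = p$N_w)
  sim <- simulate_whirs(p, init, t_end = 48, record_events = TRUE,
                        seed = 4)
  ev <- sim$events
  expect_equal(sum(ev[, "size"]), sum(sim$hourly$count))
  hour_of <- floor(ev[, "time"])
  audited <- tapply(ev[, "size"], factor(hour_of, levels = 0:47), sum)
  audited[is.na(audited)] <- 0
  expect_equal(unname(audited), sim$hourly$count, ignore_attr = TRUE)
})

test_that("with the social term off arrivals are a Poisson process", {
  # all-day window, unit batches, no departures or workers: hourly
  # arrivals over 24 h should be Poisson(24 * epsilon)
  eps <- 20
  p <- shop_params(epsilon = eps, alpha = 0, beta = 0, N_w = 0,
                   mu = 0, sigma = 0,
                   windows = list(shopper = c(0, 24),
                                  worker_in = c(0, 0),
                                  worker_out = c(0, 0)))
  set.seed(5)
  n_rep <- 500
  totals <- vapply(seq_len(n_rep), function(i) {
    init <- whirs_state(S = p$N)
    sum(simulate_whirs(p, init, t_end = 24)$hourly$count)
  }, numeric(1))
  m <- 24 * eps
  expect_lt(abs(mean(totals) - m), 2 * sqrt(m / n_rep) + 1e-9)
  expect_gt(var(totals) / mean(totals), 0.9)
  expect_lt(var(totals) / mean(totals), 1.1)
})

test_that("batch-size volatility inflates day-to-day count spread", {
  # sigma > 0 batches versus a matched-mean unit-batch baseline
  set.seed(6)
  n_days <- 200
  base <- list(alpha = 0, beta = 1, N_w = 0, N = 20000)
  pA <- do.call(shop_params, c(base, list(epsilon = 30, mu = 1,
                                          sigma = 0.5)))
  bmean <- rounded_lognormal_mean(1, 0.5)
  pB <- do.call(shop_params, c(base, list(epsilon = 30 * bmean, mu = 0,
                                          sigma = 0)))
  day_totals <- function(p) {
    vapply(seq_len(n_days), function(i) {
      init <- whirs_state(S = p$N)
      sum(simulate_whirs(p, init, t_end = 24)$hourly$count)
    }, numeric(1))
  }
  tA <- day_totals(pA); tB <- day_totals(pB)
  # similar means by construction, strictly larger spread with batches
  expect_lt(abs(mean(tA) / mean(tB) - 1), 0.05)
  expect_gt(var(tA), var(tB))
  expect_lt(stats::var.test(tA, tB, alternative = "greater")$p.value, 0.05)
})

test_that("packing matches the filter state layout and round-trips", {
  p <- shop_params()
  st <- whirs_state(S = 700, I = 80, R = 20, H_home = 150, W = 50, C = 12)
  # single-gamma layout: the documented 14-component ordering
  x14 <- whirs_pack(st, p, tie_gamma = TRUE)
  expect_equal(names(x14),
               c("S", "I", "H", "C", "N", "N_w", "alpha", "beta",
                 "epsilon", "gamma", "delta_plus", "delta_minus",
                 "sigma", "mu"))
  # default layout keeps both commuting base rates
  x <- whirs_pack(st, p)
  up <- whirs_unpack(x)
  expect_equal(up$state$S, 700)
  expect_equal(up$state$R, (p$N - p$N_w) - 700 - 80)   # derived
  expect_equal(up$state$W, p$N_w - 150)                # derived
  expect_equal(up$params$alpha, p$alpha)
  expect_equal(up$n_clamped, 0L)
  # conservation repair when the filter pushes S + I past the pool
  x_bad <- x
  x_bad[["S"]] <- p$N  # more shoppers than exist
  up2 <- whirs_unpack(x_bad)
  expect_gte(up2$state$R, 0)
  expect_equal(up2$state$S + up2$state$I + up2$state$R, p$N - p$N_w)
  expect_equal(up2$n_clamped, 1L)
})

test_that("the log mask spares only mu", {
  mask <- whirs_log_mask()
  expect_false(mask[["mu"]])
  expect_true(all(mask[names(mask) != "mu"]))
})

test_that("the evolution adapter is conservative and alpha-monotone", {
  p0 <- shop_params(epsilon = 0, alpha = 0, beta = 0, N_w = 0,
                    gamma_minus = 0, delta_minus = 0, gamma_plus = 0,
                    delta_plus = 0)
  st <- whirs_state(S = 800, t = 0)
  model <- whirs_evolution_model()
  x <- whirs_pack(st, p0)
  set.seed(7)
  y <- model(x, 0, 1)
  # no dynamics: state unchanged except the camera reading for the hour
  expect_equal(y[["S"]], 800)
  expect_equal(y[["C"]], 0)
  expect_equal(y[["alpha"]], 0)

  # rich-get-richer: the mean mid-morning count grows with alpha
  set.seed(8)
  mean_c <- vapply(c(0, 0.3, 0.6), function(a) {
    p <- shop_params(alpha = a, epsilon = 2)
    init <- whirs_state(S = p$N - p$N_w, H_home = p$N_w)
    xs <- whirs_pack(init, p)
    mean(vapply(1:200, function(i) model(xs, 0, 10)[["C"]], numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_c) > 0))
})
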