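test_that("ensemble moments use the 1/(N-1) estimator", {
  e <- ensemble(matrix(c(0, 2), ncol = 1), names = "x")
  m <- ensemble_moments(e)
  expect_equal(m$mean, c(x = 1))
  expect_equal(as.numeric(m$cov), 2)  # (1^2 + 1^2) / (2 - 1)

  # identical members: zero covariance
  e2 <- ensemble(matrix(3, 10, 2))
  expect_true(all(ensemble_moments(e2)$cov == 0))

  # brute-force two-pass oracle on random members
  set.seed(1)
  X <- matrix(rnorm(50 * 3), 50, 3)
  mom <- ensemble_moments(ensemble(X))
  mu <- colSums(X) / 50
  P <- matrix(0, 3, 3)
  for (i in 1:50) P <- P + tcrossprod(X[i, ] - mu)
  P <- P / 49
  expect_equal(unname(mom$mean), mu, tolerance = 1e-12)
  expect_equal(unname(mom$cov), P, tolerance = 1e-12)

  expect_error(ensemble_moments(ensemble(matrix(1, 1, 1))), "2 members")
})

test_that("the Kalman gain solves its defining equation", {
  expect_equal(as.numeric(kalman_gain(1, observation_model(1, 1))), 0.5)
  expect_lt(abs(kalman_gain(1, observation_model(1, 1e12))), 1e-10)

  set.seed(2)
  A <- matrix(rnorm(16), 4, 4); P <- crossprod(A)
  H <- matrix(rnorm(8), 2, 4)
  obs <- observation_model(H, diag(c(2, 3)))
  K <- kalman_gain(P, obs)
  resid <- K %*% (H %*% P %*% t(H) + obs$R) - P %*% t(H)
  expect_lt(max(abs(resid)), 1e-10)

  expect_error(kalman_gain(matrix(0, 1, 1),
                           observation_model(1, matrix(0, 1, 1))),
               "regularize")
})

test_that("assimilation collapses onto the data when R -> 0", {
  set.seed(3)
  fc <- ensemble(matrix(rnorm(100, 10), ncol = 1), names = "x")
  st <- assimilate(fc, z = 7, obs = observation_model(1, 1e-12),
                   perturb = FALSE)
  expect_lt(max(abs(st$analysis_members - 7)), 1e-4)
})

test_that("assimilation leaves the ensemble alone when R -> Inf", {
  set.seed(4)
  fc <- ensemble(matrix(rnorm(200, 10), ncol = 1), names = "x")
  st <- assimilate(fc, z = 0, obs = observation_model(1, 1e16))
  expect_lt(max(abs(st$analysis_members - fc$members)), 1e-6)
})

test_that("scalar analysis variance contracts as (1-K) P_f", {
  set.seed(5)
  Pf <- 4; R <- 16
  fc <- ensemble(matrix(rnorm(2000, 50, sqrt(Pf)), ncol = 1), names = "x")
  st <- assimilate(fc, z = 50, obs = observation_model(1, R))
  K <- unname(st$gain[1, 1])
  expect_equal(K, Pf / (Pf + R), tolerance = 0.1)
  expect_equal(as.numeric(st$analysis_cov),
               unname((1 - K) * as.numeric(st$forecast_cov)),
               tolerance = 0.05)
})

test_that("analysis spread is below forecast spread in expectation", {
  set.seed(6)
  vars <- replicate(100, {
    fc <- ensemble(matrix(rnorm(50, 0, 2), ncol = 1), names = "x")
    st <- assimilate(fc, z = 0, obs = observation_model(1, 4))
    c(f = as.numeric(st$forecast_cov), a = as.numeric(st$analysis_cov))
  })
  expect_lt(mean(vars["a", ]), mean(vars["f", ]))
})

test_that("virtual-observation noise has the configured covariance", {
  set.seed(7)
  R <- matrix(c(4, 1, 1, 2), 2, 2)
  fc <- ensemble(matrix(rnorm(2 * 1e4), ncol = 2))
  st <- assimilate(fc, z = c(0, 0), obs = observation_model(diag(2), R))
  nu <- st$virtual_obs  # z = 0, so virtual obs are the noise draws
  expect_lt(max(abs(colMeans(nu))), 3 * sqrt(max(diag(R)) / 1e4))
  expect_lt(max(abs(cov(nu) - R) / max(R)), 0.05)
})

test_that("forecasting evolves members independently and in order", {
  e <- ensemble(matrix(1:6, ncol = 1), names = "x", time = 0)
  ident <- function(x, t0, t1) x
  out <- forecast_ensemble(e, ident, 1)
  expect_equal(out$members, e$members)
  expect_equal(out$time, 1)

  # a deterministic state-dependent model: permuting members permutes
  # outputs identically
  dbl <- function(x, t0, t1) 2 * x
  perm <- c(4, 2, 6, 1, 3, 5)
  a <- forecast_ensemble(e, dbl, 1)$members[perm, ]
  ep <- ensemble(e$members[perm, , drop = FALSE], names = "x", time = 0)
  b <- forecast_ensemble(ep, dbl, 1)$members
  expect_equal(a, b, ignore_attr = TRUE)

  bad <- function(x, t0, t1) c(x = NaN)
  expect_error(forecast_ensemble(e, bad, 1), "member 1")
  expect_error(forecast_ensemble(e, ident, 0), "later")
})

test_that("forecasting the box ensemble reproduces the mean solution", {
  p <- box_params(52.52, 0.2580)
  set.seed(8)
  N <- 1000
  e <- ensemble(matrix(200, N, 1), names = "x", time = 0)
  fc <- forecast_ensemble(e, box_evolution_model(p), 1)
  u1 <- mean_solution(p, 200, 1)          # 200.81
  v1 <- variance_solution(p, 200, 0, 1)
  se <- sqrt(v1 / N)
  expect_lt(abs(mean(fc$members) - u1), 2 * se + 1e-9)
})

test_that("log transform round-trips, clamps at the floor, spares mu", {
  v <- c(S = 10, C = 0.2, mu = -1.3)
  mask <- c(TRUE, TRUE, FALSE)
  lt <- log_transform(v, mask, floor = 1)
  expect_equal(unname(lt["S"]), log(10))
  expect_equal(unname(lt["C"]), 0)        # clamped 0.2 -> 1 -> log 1
  expect_equal(unname(lt["mu"]), -1.3)    # unmasked passthrough
  expect_equal(attr(lt, "clamped"), 1L)
  back <- inverse_log_transform(lt, mask)
  expect_equal(unname(back["S"]), 10)
  expect_equal(unname(back["mu"]), -1.3)
  # exact round trip above the floor
  w <- c(a = 2.5, b = 100)
  expect_equal(inverse_log_transform(log_transform(w, TRUE), TRUE), w)
})

test_that("state augmentation round-trips and flags unknown names", {
  s <- c(x = 3); th <- c(alpha = 50, beta = 0.25)
  aug <- augment_parameters(s, th)
  expect_equal(names(aug), c("x", "alpha", "beta"))
  back <- project_back(aug, "x")
  expect_equal(back$state, s)
  expect_equal(back$params, th)
  expect_error(project_back(aug, "y"), "unknown component")
  expect_error(augment_parameters(c(x = 1), c(x = 2)), "clash")
})

test_that("EnKF matches the exact Kalman filter on a linear system", {
  a <- 0.9; Q <- 4; R <- 4
  set.seed(10)
  T_steps <- 4
  x <- 50
  z <- numeric(T_steps)
  for (k in 1:T_steps) {
    x <- a * x + rnorm(1, 0, sqrt(Q))
    z[k] <- x + rnorm(1, 0, sqrt(R))
  }
  kf <- exact_kalman(z, a, Q, R, m0 = 50, P0 = 9)
  N <- 1e4
  init <- ensemble(matrix(rnorm(N, 50, 3), ncol = 1), names = "x")
  run <- run_filter(linear_gaussian_model(a, Q),
                    list(times = 1:T_steps, z = z),
                    observation_model(1, R), init)
  am <- vapply(run$steps, function(s) s$analysis_mean[["x"]], numeric(1))
  av <- vapply(run$steps, function(s) as.numeric(s$analysis_cov),
               numeric(1))
  expect_lt(max(abs(am - kf$mean) / abs(kf$mean)), 0.02)
  expect_lt(max(abs(av - kf$var) / kf$var), 0.05)
})

test_that("a full filter run is bit-identical under the same seed", {
  p <- box_params(50, 0.25)
  obs <- observation_model(1, 16)
  run_once <- function() {
    set.seed(33)
    init <- ensemble(matrix(rounded_normal(30, 200, sqrt(200)), ncol = 1),
                     names = "x")
    run_filter(box_evolution_model(p), list(times = 1:10,
                                            z = rep(200, 10)),
               obs, init, config = list(round_components = "x"))
  }
  r1 <- run_once(); r2 <- run_once()
  expect_identical(
    lapply(r1$steps, `[[`, "analysis_mean"),
    lapply(r2$steps, `[[`, "analysis_mean"))
  expect_identical(r1$final_ensemble$members, r2$final_ensemble$members)
})

test_that("an empty observation set yields a pure forecast", {
  e <- ensemble(matrix(1:5, ncol = 1), names = "x", time = 0)
  run <- run_filter(function(x, t0, t1) x + (t1 - t0),
                    list(times = numeric(0), z = numeric(0)),
                    observation_model(1, 1), e,
                    config = list(t_end = 3))
  expect_length(run$steps, 0)
  expect_equal(run$final_ensemble$time, 3)
  expect_equal(as.numeric(run$final_ensemble$members), (1:5) + 3)
})
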