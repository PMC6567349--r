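test_that("prediction propagates the balance model and inflates variance", {
  p <- const_evap(5) # 10 g per 2 h step
  ks <- kalman_state(q = 0.001, w_hat = 1.0, p = 0.01)
  # balanced irrigation leaves the estimate unchanged, P grows by q
  ks1 <- kf_predict(ks, 10, 28, 2, 45, p)
  expect_equal(ks1$w_hat, 1.0, tolerance = 1e-9)
  expect_equal(ks1$p, 0.011)
  # q = 0: repeated balanced predicts never change the state
  ks0 <- kalman_state(q = 0, w_hat = 1.0, p = 0.01)
  for (i in 1:5) ks0 <- kf_predict(ks0, 10, 28, 2, 45, p)
  expect_equal(ks0$w_hat, 1.0, tolerance = 1e-9)
  expect_equal(ks0$p, 0.01)
})

test_that("unforced prediction matches the plant trajectory for a nominal sheet", {
  p <- evap_params()
  s <- sheet_state("a", W = 1.3, m_GP = 45, W_max = 1.9)
  ks <- kalman_state(q = 0, w_hat = 1.3, p = 0)
  for (k in 1:10) {
    s <- step_water_balance(s, 0, 27, 2, p, process_sd = 0)
    ks <- kf_predict(ks, 0, 27, 2, 45, p)
    expect_equal(ks$w_hat, s$W, tolerance = 1e-9)
  }
})

test_that("measurement update implements the scalar gain correctly", {
  curves <- list(p1 = flat_curve(0.2)) # r = 0.01
  m <- data.frame(raw_water_content = 1.2, in_effective_range = TRUE,
                  position = 1L)
  # diffuse prior: estimate jumps to the measurement
  ks <- kalman_state(curves = curves, w_hat = 0.5, p = 1e9)
  expect_equal(kf_update(ks, m)$w_hat, 1.2, tolerance = 1e-6)
  # near-infinite r (wide band): estimate unchanged
  wide <- list(p1 = flat_curve(2e6))
  ks2 <- kalman_state(curves = wide, w_hat = 0.5, p = 0.01)
  expect_equal(kf_update(ks2, m)$w_hat, 0.5, tolerance = 1e-6)
  # gain stays in [0, 1] and P never increases across an update
  ks3 <- kalman_state(curves = curves, w_hat = 1.0, p = 0.02)
  up <- kf_update(ks3, m)
  k_gain <- (up$w_hat - 1.0) / (1.2 - 1.0)
  expect_gte(k_gain, 0)
  expect_lte(k_gain, 1)
  expect_lte(up$p, ks3$p)
  # out-of-range measurements are skipped
  m_out <- data.frame(raw_water_content = 1.2, in_effective_range = FALSE,
                      position = 1L)
  expect_equal(kf_update(ks3, m_out), ks3)
})

test_that("filtered series equals the batch weighted-least-squares oracle", {
  set.seed(13)
  q <- 4e-4
  r <- 1e-2
  E0 <- 5 # g/h; 10 g per step
  p <- const_evap(E0)
  n <- 25
  irr <- sample(seq(0, 30, 5), n, replace = TRUE)
  u <- (irr - E0 * 2) / 45
  x0 <- 1.0
  P0 <- 0.05
  # simulate the linear-Gaussian truth
  x <- numeric(n)
  xk <- x0
  for (k in 1:n) {
    xk <- xk + u[k] + rnorm(1, 0, sqrt(q))
    x[k] <- xk
  }
  y <- x + rnorm(n, 0, sqrt(r))
  # run the recursive filter
  curves <- list(p1 = flat_curve(2 * sqrt(r)))
  ks <- kalman_state(q = q, curves = curves, w_hat = x0, p = P0)
  w_hat <- numeric(n)
  for (k in 1:n) {
    ks <- kf_predict(ks, irr[k], 28, 2, 45, p)
    ks <- kf_update(ks, data.frame(raw_water_content = y[k],
                                   in_effective_range = TRUE,
                                   position = 1L))
    w_hat[k] <- ks$w_hat
  }
  oracle <- batch_wls_oracle(y, u, x0, P0, q, r)
  expect_equal(w_hat, oracle, tolerance = 1e-8)
})

test_that("a gross outlier moves the estimate by less than gain times its size", {
  curves <- list(p1 = flat_curve(0.2))
  ks <- kalman_state(q = 4e-4, curves = curves, w_hat = 1.0, p = 2e-3)
  k_gain <- ks$p / (ks$p + 0.01)
  up <- kf_update(ks, data.frame(raw_water_content = 1.5,
                                 in_effective_range = TRUE, position = 1L))
  expect_lte(abs(up$w_hat - 1.0), k_gain * 0.5 + 1e-12)
})

test_that("filter_series handles gaps, misalignment, and near-noiseless data", {
  p <- const_evap(5)
  curves <- list(p1 = flat_curve(1e-6))
  n <- 20
  irr <- rep(10, n) # balanced
  H <- rep(28, n)
  truth <- rep(1.0, n)
  raw <- data.frame(raw_water_content = truth, in_effective_range = TRUE,
                    position = 1L)
  out <- filter_series(raw, irr, H, 2, 45, p,
                       ks = kalman_state(q = 1e-6, curves = curves))
  expect_equal(out$w_hat, truth, tolerance = 1e-6)
  # unmeasured slots (NA raw) are predict-only and keep the trajectory
  raw_gap <- raw
  raw_gap$raw_water_content[seq(2, 18, 2)] <- NA
  out_gap <- filter_series(raw_gap, irr, H, 2, 45, p,
                           ks = kalman_state(q = 1e-6, curves = curves))
  expect_equal(out_gap$w_hat, truth, tolerance = 1e-5)
  expect_error(filter_series(raw, irr[-1], H, 2, 45, p), "aligned")
})

test_that("filtering beats the raw channel on banded-noise trajectories", {
  p <- evap_params()
  curves <- default_calibration_curves()
  err_f <- err_r <- numeric(30)
  for (seed in 1:30) {
    set.seed(seed)
    s <- sheet_state("a", W = 1.2, m_GP = 45, W_max = 1.9)
    ks <- kalman_state(q = 0.02^2, curves = curves)
    ef <- er <- c()
    for (k in 1:54) { # 4.5 days
      irr <- quantize_action(gp_evaporation(p, 27, s$W, 45) * 2)
      m <- simulate_raw_measurement(s$W, curves$p1)
      ks <- kf_update(ks, m)
      if (ks$initialized) {
        ef <- c(ef, abs(ks$w_hat - s$W))
        er <- c(er, abs(m$raw_water_content - s$W))
      }
      s <- step_water_balance(s, irr, 27, 2, p, process_sd = 0.02)
      ks <- kf_predict(ks, irr, 27, 2, 45, p)
    }
    err_f[seed] <- mean(ef)
    err_r[seed] <- mean(er)
  }
  expect_lt(mean(err_f), mean(err_r))
})

test_that("rail updates pull a stranded estimate back toward the range boundary", {
  curves <- default_calibration_curves()
  ks <- kalman_state(q = 4e-4, curves = curves, w_hat = 0.95, p = 2e-3)
  # dry-railed reading at position 2: sheet is drier than 0.45
  m <- data.frame(raw_water_content = 0.2, in_effective_range = FALSE,
                  position = 2L)
  up <- kf_rail_update(ks, m)
  expect_lt(up$w_hat, ks$w_hat)
  expect_gte(up$w_hat, 0.45)
  # estimate already on the censoring side: no change
  ks_low <- kalman_state(q = 4e-4, curves = curves, w_hat = 0.3, p = 2e-3)
  expect_equal(kf_rail_update(ks_low, m), ks_low)
  # in-range measurements are not rail-updated
  m_in <- data.frame(raw_water_content = 0.5, in_effective_range = TRUE,
                     position = 2L)
  expect_equal(kf_rail_update(ks, m_in), ks)
})
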