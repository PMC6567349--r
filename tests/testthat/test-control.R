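test_that("internal integrator model steps as T0/T1 on the held input", {
  cfg <- controller_config("MPC")
  expect_equal(plant_model_step(1.0, 0, cfg), 1.0)
  # 9 mL over T1 = 45 g: +0.2 g/g
  expect_equal(plant_model_step(1.0, 9, cfg), 1.2)
  # linearity: N steps of I, then remove N*I in one step -> back to start
  w <- 0.8
  for (k in 1:4) w <- plant_model_step(w, 10, cfg)
  expect_equal(w - 4 * 10 / 45, 0.8, tolerance = 1e-12)
  # with feed-forward the evaporation drain is subtracted
  p <- const_evap(5)
  expect_equal(plant_model_step(1.0, 0, cfg, H = 28, params = p),
               1.0 - 10 / 45, tolerance = 1e-9)
})

test_that("quantization projects to the nearest volume, ties downward", {
  acts <- seq(0, 30, 5)
  expect_equal(quantize_action(12.4, acts), 10)
  expect_equal(quantize_action(12.6, acts), 15)
  expect_equal(quantize_action(12.5, acts), 10) # tie -> smaller
  expect_equal(quantize_action(c(-3, 0.4, 31), acts), c(0, 0, 30))
})

test_that("PI difference equation expands as expected on a unit-step error", {
  cfg <- controller_config("PI", gain_volume_per_error = 1)
  u <- 0
  e_prev <- 0
  raw <- numeric(4)
  for (k in 1:4) {
    st <- pi_step(1, e_prev, u, cfg, clamp = FALSE)
    raw[k] <- st$raw
    u <- st$raw
    e_prev <- 1
  }
  expect_equal(raw, c(1, 1.4, 1.8, 2.2), tolerance = 1e-12)
  # zero error from rest stays at rest
  expect_equal(pi_step(0, 0, 0, cfg)$command, 0)
  # commands always lie in the action set
  cfg45 <- controller_config("PI")
  set.seed(2)
  for (k in 1:50) {
    st <- pi_step(runif(1, -1, 1), runif(1, -1, 1), runif(1, 0, 30), cfg45)
    expect_true(st$command %in% cfg45$action_set)
  }
})

test_that("PI rejects a constant disturbance without steady-state error", {
  # unquantized loop: integrator model + constant evaporation drain
  cfg <- controller_config("PI", gain_volume_per_error = 45)
  p <- const_evap(5) # 10 g per step leaves the sheet
  w <- 0.89
  ref <- 0.89
  u <- 0
  e_prev <- 0
  for (k in 1:300) {
    e <- ref - w
    st <- pi_step(e, e_prev, u, cfg, clamp = FALSE)
    u <- st$raw
    e_prev <- e
    w <- w + (st$raw - 10) / 45 # apply the raw (unquantized) volume
  }
  expect_equal(w, ref, tolerance = 1e-6)
  expect_equal(u, 10, tolerance = 1e-4) # integrator carries the disturbance
})

test_that("explicit two-action enumeration picks the better fill", {
  cfg <- controller_config("MPC", action_set = c(0, 30), horizon = 1)
  p <- const_evap(2.5) # 5 g per step
  cmd <- mpc_step(0.5, 0.89, 28, cfg, p, m_GP = 45)
  # I = 0 -> W = 0.389 (err 0.501); I = 30 -> W ~ 1.0556 (err ~0.166)
  expect_equal(as.numeric(cmd), 30)
  expect_equal(attr(cmd, "cost"), (0.89 - (0.5 + 30 / 45 - 5 / 45))^2,
               tolerance = 1e-6)
  # already on target with no evaporation: do nothing
  cfg0 <- controller_config("MPC", horizon = 2, use_feedforward = FALSE)
  expect_equal(as.numeric(mpc_step(0.89, 0.89, 28, cfg0, null_evap())), 0)
})

test_that("MPC equals the brute-force enumeration oracle", {
  p <- evap_params()
  set.seed(31)
  for (rep in 1:100) {
    cfg <- controller_config("MPC", horizon = sample(1:3, 1),
                             use_feedforward = sample(c(TRUE, FALSE), 1))
    w <- runif(1, 0.2, 1.8)
    ref <- runif(cfg$horizon, 0.4, 1.2)
    H <- runif(1, 21, 33)
    got <- mpc_step(w, ref, H, cfg, p)
    want <- mpc_oracle(w, ref, H, cfg, p)
    expect_equal(as.numeric(got), want$first)
    expect_equal(attr(got, "cost"), want$cost, tolerance = 1e-10)
  }
})

test_that("MPC cost is translation-invariant for the pure integrator model", {
  cfg <- controller_config("MPC", horizon = 3, use_feedforward = FALSE)
  p <- null_evap()
  set.seed(5)
  for (rep in 1:20) {
    w <- runif(1, 0.5, 1.2)
    ref <- runif(3, 0.5, 1.2)
    shift <- runif(1, -0.2, 0.4)
    a <- mpc_step(w, ref, 28, cfg, p)
    b <- mpc_step(w + shift, ref + shift, 28, cfg, p)
    expect_equal(as.numeric(a), as.numeric(b))
  }
})

test_that("commands never leave the quantized action set", {
  p <- evap_params()
  cfg <- controller_config("MPC")
  set.seed(6)
  for (rep in 1:50) {
    cmd <- as.numeric(mpc_step(runif(1, 0, 2), runif(1, 0.3, 1.2),
                               runif(1, 21, 33), cfg, p))
    expect_true(cmd %in% cfg$action_set)
  }
  expect_error(controller_config("MPC", horizon = 5), "<= 4")
})

test_that("group control averages the measured sheets and holds on dropout", {
  cfg <- controller_config("MPC")
  p <- evap_params()
  # identical estimates reduce to individual control on that estimate
  g <- group_step(c(0.8, 0.8), c(0.89, 0.89, 0.89), 27, cfg, p)
  ind <- mpc_step(0.8, c(0.89, 0.89, 0.89), 27, cfg, p)
  expect_equal(g$command, as.numeric(ind))
  # mean of two distinct estimates feeds the controller
  g2 <- group_step(c(0.8, 1.0), c(0.89, 0.89, 0.89), 27, cfg, p)
  expect_equal(g2$mean_estimate, 0.9)
  expect_equal(g2$command,
               as.numeric(mpc_step(0.9, c(0.89, 0.89, 0.89), 27, cfg, p)))
  # no valid measurement: previous command is repeated
  g3 <- group_step(c(NA, NA), 0.89, 27, cfg, p, prev_command = 15)
  expect_equal(g3$command, 15)
})

test_that("a homogeneous cohort makes group and individual control coincide", {
  proto <- gp_protocol(data.frame(days = 2, w = 0.89))
  curves <- exact_curves()
  run <- function(mode) {
    cohort <- make_cohort(2, seed = 4, sdlog = 0)
    cohort$sheet1$W_max <- cohort$sheet2$W_max <- 1.9
    run_experiment(proto, cohort, mode, controller_config("MPC"),
                   evap_params(), curves, seed = 4, process_sd = 0,
                   humidity_sd = 0)
  }
  ind <- run(control_mode("individual", c("sheet1", "sheet2")))
  grp <- run(control_mode("group", c("sheet1", "sheet2"),
                          c("sheet1", "sheet2")))
  expect_equal(grp$log$W_true, ind$log$W_true, tolerance = 1e-6)
  expect_equal(grp$log$command_mL, ind$log$command_mL)
})
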