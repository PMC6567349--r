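test_that("discharge law matches direct evaluation and handles limits", {
  cp <- circuit_params(series_capacitance = 1575e-6, initial_charge = 1)
  # direct evaluation of the exponential decay
  expect_equal(remaining_charge(cp, 1e8), exp(-180 / (1e8 * 1575e-6)),
               tolerance = 1e-12)
  expect_equal(remaining_charge(cp, 1e8), 0.998858, tolerance = 1e-6)
  # infinite resistance: no discharge
  expect_equal(remaining_charge(cp, Inf), 1)
  expect_error(remaining_charge(cp, -5), "positive")
  expect_error(remaining_charge(cp, 0), "positive")
})

test_that("resistance recovery is the exact inverse of the discharge law", {
  cp <- circuit_params(series_capacitance = 0.001575, initial_charge = 1)
  # arithmetic case: Q0/Q = e
  expect_equal(resistance_from_charge(cp, exp(-1)), 180 / 0.001575,
               tolerance = 1e-12)
  # round trip over six decades of resistance
  r <- 10^seq(3, 9, by = 0.25)
  expect_equal(resistance_from_charge(cp, remaining_charge(cp, r)), r,
               tolerance = 1e-9)
  # remaining == Q0 gives the infinite-resistance sentinel
  expect_warning(ri <- resistance_from_charge(cp, 1), "sentinel")
  expect_identical(ri, Inf)
  expect_error(resistance_from_charge(cp, 0), "positive")
  expect_error(resistance_from_charge(cp, 1.5), "exceeds")
})

test_that("characteristic curves evaluate, flag range, and invert", {
  const <- calibration_curve(1, slope = 0, intercept = 1.0, c(0.8, 1.64))
  expect_equal(water_from_charge(const, c(1e-4, 1e-2, 1))$water,
               c(1, 1, 1))
  cv <- default_calibration_curves()
  q <- charge_from_water(cv$p1, c(0.9, 1.2, 1.5))
  out <- water_from_charge(cv$p1, q)
  expect_equal(out$water, c(0.9, 1.2, 1.5), tolerance = 1e-12)
  expect_true(all(out$in_effective_range))
  expect_false(water_from_charge(cv$p1, charge_from_water(cv$p1, 1.9))$in_effective_range)
  # monotone in remaining charge when slope > 0
  up <- calibration_curve(1, slope = 0.5, intercept = 0,
                          effective_range = c(0.8, 1.64))
  grid <- seq(0.01, 2, length.out = 50)
  expect_true(all(diff(water_from_charge(up, grid)$water) > 0))
  expect_error(water_from_charge(cv$p1, c(1e-3, -1)), "positive")
})

test_that("calibration fitting recovers log-linear parameters", {
  set.seed(11)
  a <- -0.7
  b <- -1.5
  q <- exp(seq(-5, -1, length.out = 12))
  pts <- data.frame(charge_C = q, water_g_per_g = a * log(q) + b)
  cu <- fit_calibration(pts, position = 1)
  expect_equal(cu$slope, a, tolerance = 1e-8)
  expect_equal(cu$intercept, b, tolerance = 1e-8)
  # fit consistency: training targets reproduced exactly
  expect_equal(water_from_charge(cu, q)$water, pts$water_g_per_g,
               tolerance = 1e-8)
  expect_lt(attr(cu, "fit")$max_abs_residual, 1e-10)
  # preconditions
  expect_error(fit_calibration(pts[1:2, ], 1), "at least 3")
  pts_deg <- data.frame(charge_C = rep(0.01, 5),
                        water_g_per_g = seq(0.5, 1.5, length.out = 5))
  expect_error(fit_calibration(pts_deg, 1), "degenerate")
})

test_that("symmetric noise leaves the fitted slope unbiased", {
  set.seed(42)
  a <- -0.7
  b <- -1.5
  q <- exp(seq(-5, -1, length.out = 20))
  delta <- 0.05
  err <- replicate(1000, {
    w <- a * log(q) + b + runif(length(q), -delta, delta)
    fit_calibration(data.frame(charge_C = q, water_g_per_g = w), 1)$slope - a
  })
  expect_lt(abs(mean(err)), delta / 10)
})

test_that("band noise respects closed-band maxima", {
  cv <- default_calibration_curves()
  set.seed(5)
  raw <- replicate(1e4,
    simulate_raw_measurement(1.2, cv$p1)$raw_water_content)
  # band 1.015-1.655 at position 1 has accuracy +/-0.16
  expect_lte(max(abs(raw - 1.2)), 0.16)
  expect_gt(max(abs(raw - 1.2)), 0.10) # noise actually present
  # zero-accuracy channel returns the truth
  exact <- exact_curves(1e-9)
  s <- simulate_raw_measurement(1.2, exact$p1, seed = 1)
  expect_equal(s$raw_water_content, 1.2, tolerance = 1e-7)
})

test_that("saturated out-of-range readings stay outside the effective range", {
  cv <- default_calibration_curves()
  set.seed(6)
  # truth below both ranges: position 1 reads at or below its dry rail
  raw_dry <- replicate(2000,
    simulate_raw_measurement(0.30, cv$p1)$raw_water_content)
  expect_true(all(raw_dry < 0.80))
  # truth far above position 2's range: wet rail readings, never in range
  raw_wet <- replicate(2000,
    simulate_raw_measurement(1.40, cv$p2)$raw_water_content)
  expect_true(all(raw_wet > 0.66))
  # deviations in exceedance bands do exceed the 0.67 g/g table floor
  expect_gt(max(abs(raw_wet - 1.40)), 0.67)
})

test_that("whole-range raw mean absolute deviation is calibrated near 0.44 g/g", {
  cv <- default_calibration_curves()
  set.seed(8)
  w <- runif(1e4, 0.45, 1.8)
  dev1 <- vapply(w[1:5000], function(x)
    abs(simulate_raw_measurement(x, cv$p1)$raw_water_content - x), 0)
  dev2 <- vapply(w[5001:1e4], function(x)
    abs(simulate_raw_measurement(x, cv$p2)$raw_water_content - x), 0)
  mad <- mean(c(mean(dev1), mean(dev2)))
  expect_gt(mad, 0.44 * 0.8)
  expect_lt(mad, 0.44 * 1.2)
})

test_that("position selection and fallback pick the informative contact", {
  expect_identical(select_position(c(0.9, 0.73, 0.5)), c(1L, 1L, 2L))
  cv <- default_calibration_curves()
  expect_identical(fallback_position(2.3, cv), 1L)
  expect_identical(fallback_position(0.2, cv), 2L)
  expect_identical(fallback_position(0.70, cv), 2L) # dead zone, nearer p2
})

test_that("accuracy-band tables are validated", {
  for (p in 1:2) {
    b <- default_accuracy_bands(p)
    expect_equal(b$w_lo[1], 0)
    expect_true(is.infinite(b$w_hi[nrow(b)]))
    expect_equal(b$w_lo[-1], b$w_hi[-nrow(b)]) # contiguous cover
  }
  bad <- default_accuracy_bands(1)
  bad$w_hi[2] <- 0.5 # opens a gap
  expect_error(calibration_curve(1, -1, 0, c(0.8, 1.64), bands = bad),
               "contiguous")
  # bands overlapping the effective range must be accurate enough
  expect_error(calibration_curve(2, -1, 0, c(0.45, 0.80)),
               "effective range")
})
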