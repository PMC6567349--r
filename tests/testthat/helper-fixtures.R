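# Shared fixtures and independent oracles, built in code at test time.

# A curve with one flat closed band: constant measurement variance
# (accuracy / 2)^2 everywhere and an arbitrarily wide effective range --
# turns the band machinery into a plain linear-Gaussian channel.
flat_curve <- function(accuracy = 0.2, position = 1,
                       effective_range = c(-1e6, 1e6)) {
  bands <- data.frame(w_lo = 0, w_hi = Inf, accuracy = accuracy,
                      exceedance = FALSE)
  calibration_curve(position, slope = -1, intercept = 0,
                    effective_range = effective_range, bands = bands,
                    max_effective_accuracy = accuracy)
}

# Near-zero, W-independent evaporation: keeps the water balance linear.
null_evap <- function() {
  evap_params(c1 = 0, c2 = 1e-9, c3 = 0, c4 = 0, rate_scale = 1)
}

# Constant evaporation rate E0 (g/h), independent of H and W, so the
# balance is exactly the linear integrator x' = x + (I - E0 * T0) / m.
const_evap <- function(E0) {
  evap_params(c1 = 0, c2 = 1e-9, c3 = 0, c4 = E0, rate_scale = 1)
}

# Near-noiseless measurement channel for both positions (closed band with
# tiny accuracy), keeping the standard effective ranges.
exact_curves <- function(accuracy = 1e-6) {
  list(p1 = flat_curve(accuracy, 1, c(0.80, 1.64)),
       p2 = flat_curve(accuracy, 2, c(0.45, 0.66)))
}

# Batch MAP/weighted-least-squares oracle for the scalar random-walk
# state-space model x_k = x_{k-1} + u_k + w_k, y_k = x_k + v_k, with prior
# x_0 ~ N(x0, P0), Var(w) = q, Var(v) = r. Returns for each k the MAP
# estimate of x_k given y_1..k, obtained by solving the full normal
# equations -- independent of the recursive filter it checks.
batch_wls_oracle <- function(y, u, x0, P0, q, r) {
  n <- length(y)
  out <- numeric(n)
  for (k in seq_len(n)) {
    m <- k + 1 # unknowns x_0 .. x_k
    A <- matrix(0, m, m)
    b <- numeric(m)
    A[1, 1] <- 1 / P0
    b[1] <- x0 / P0
    for (j in seq_len(k)) {
      # process link x_j - x_{j-1} = u_j + w_j
      A[j, j] <- A[j, j] + 1 / q
      A[j + 1, j + 1] <- A[j + 1, j + 1] + 1 / q
      A[j, j + 1] <- A[j, j + 1] - 1 / q
      A[j + 1, j] <- A[j + 1, j] - 1 / q
      b[j + 1] <- b[j + 1] + u[j] / q
      b[j] <- b[j] - u[j] / q
      # measurement y_j on x_j
      A[j + 1, j + 1] <- A[j + 1, j + 1] + 1 / r
      b[j + 1] <- b[j + 1] + y[j] / r
    }
    out[k] <- solve(A, b)[m]
  }
  out
}

# Brute-force MPC oracle: explicit nested enumeration of every action
# sequence, simulated with its own arithmetic.
mpc_oracle <- function(W_hat, ref, H, cfg, params, m_GP = cfg$T1) {
  acts <- cfg$action_set
  h <- cfg$horizon
  ref <- rep_len(ref, h)
  best_cost <- Inf
  best_first <- NA_real_
  idx <- rep(1L, h)
  repeat {
    seqa <- acts[idx]
    w <- W_hat
    cost <- 0
    for (j in seq_len(h)) {
      w <- w + seqa[j] / cfg$T1
      if (cfg$use_feedforward) {
        w <- w - gp_evaporation(params, H, max(w - seqa[j] / cfg$T1, 1e-6),
                                m_GP) * cfg$T0 / m_GP
      }
      w <- max(w, 0)
      cost <- cost + (ref[j] - w)^2
    }
    if (cost < best_cost - 1e-15) {
      best_cost <- cost
      best_first <- seqa[1]
    }
    # odometer increment, first position most significant: enumeration
    # order is lexicographic, so ties keep the smaller sequence
    j <- h
    while (j >= 1) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= length(acts)) break
      idx[j] <- 1L
      j <- j - 1L
    }
    if (j < 1) break
  }
  list(first = best_first, cost = best_cost)
}

# Standard group-control setup: 5 sheets, sheets 1-2 measured.
group_mode_5 <- function() {
  control_mode("group", c("sheet1", "sheet2"), paste0("sheet", 1:5))
}
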