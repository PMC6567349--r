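#' State of one germination-paper sheet
#'
#' The "plant" in control terms: true gravimetric water content `W` and the
#' physical properties of one GP sheet. `W_max` is the saturation content
#' (sheets saturate between 1.78 and 2.00 g/g), `evap_multiplier` a
#' dimensionless per-sheet factor on the evaporation rate representing
#' sheet-to-sheet heterogeneity (the reason identically irrigated sheets
#' drift apart).
#'
#' @param sheet_id Identifier.
#' @param W Water content, g/g, in `[0, W_max]`.
#' @param m_GP Dry mass in gram (default 45, a standard 210 x 297 mm sheet).
#' @param W_max Saturation water content, g/g.
#' @param evap_multiplier Positive per-sheet evaporation factor.
#' @return An object of class `sheet_state`.
#' @export
sheet_state <- function(sheet_id, W = 0.89, m_GP = 45, W_max = 1.89,
                        evap_multiplier = 1) {
  stopifnot(
    is.numeric(W), length(W) == 1L, is.numeric(W_max), W_max > 0,
    W >= 0, W <= W_max, is.numeric(m_GP), m_GP > 0,
    is.numeric(evap_multiplier), evap_multiplier > 0
  )
  structure(
    list(sheet_id = as.character(sheet_id), W = W, m_GP = m_GP,
         W_max = W_max, evap_multiplier = evap_multiplier),
    class = "sheet_state"
  )
}

#' @export
print.sheet_state <- function(x, ...) {
  cat(sprintf("<sheet_state> %s: W = %.3f g/g (W_max = %.2f), m_GP = %g g, evap x%.3f\n",
              x$sheet_id, x$W, x$W_max, x$m_GP, x$evap_multiplier))
  invisible(x)
}

#' Generate a cohort of heterogeneous GP sheets
#'
#' Draws per-sheet saturation `W_max ~ Uniform(1.78, 2.00)` g/g and
#' evaporation multipliers `~ lognormal(meanlog = 0, sdlog)` (default
#' `sdlog = 0.1`, i.e. about 10% sheet-to-sheet spread in evaporation rate).
#' Initial water content is identical across sheets unless changed. With
#' `sdlog = 0` all sheets are physically identical and diverge only through
#' measurement/actuation noise.
#'
#' @param n Number of sheets (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @param initial_w Common initial water content, g/g (default 0.89).
#' @param m_GP Dry mass in gram.
#' @param wmax_range Length-2 range for the uniform `W_max` draw.
#' @param sdlog sdlog of the lognormal evaporation multiplier.
#' @return A list of [sheet_state()] objects named `sheet1` ... `sheetn`.
#' @export
make_cohort <- function(n, seed = NULL, initial_w = 0.89, m_GP = 45,
                        wmax_range = c(1.78, 2.00), sdlog = 0.1) {
  stopifnot(n >= 1, sdlog >= 0, wmax_range[1] <= wmax_range[2])
  if (!is.null(seed)) set.seed(seed)
  wmax <- stats::runif(n, wmax_range[1], wmax_range[2])
  mult <- if (sdlog > 0) stats::rlnorm(n, 0, sdlog) else rep(1, n)
  out <- lapply(seq_len(n), function(i) {
    sheet_state(paste0("sheet", i), W = initial_w, m_GP = m_GP,
                W_max = wmax[i], evap_multiplier = mult[i])
  })
  names(out) <- vapply(out, `[[`, "", "sheet_id")
  out
}

#' Advance one sheet's water balance by one sampling interval
#'
#' Discrete water balance
#' `m_GP * W' = m_GP * W + absorbed - evap_multiplier * E(H, W) * T0 (+ noise)`,
#' clamped to `[0, W_max]`. Absorption follows the observed tank behaviour:
#' below 0.67 g/g the sheet takes up the full offered volume within one
#' interval; above that it is capacity-limited, `min(volume, (W_max - W) *
#' m_GP)`. The optional zero-mean Gaussian process noise (sd in g/g per
#' step) represents unmodelled disturbances (drafts, temperature swings,
#' spatial redistribution).
#'
#' @param state A [sheet_state()].
#' @param irrigation_ml Irrigation volume in mL (1 mL of nutrient solution
#'   weighs 1 g), >= 0.
#' @param H Relative humidity in percent.
#' @param T0 Sampling interval in hours (default 2).
#' @param params An [evap_params()] object.
#' @param process_sd Process-noise standard deviation in g/g per step
#'   (default 0.02; 0 disables it).
#' @param seed Optional integer seed.
#' @return The updated [sheet_state()], with bookkeeping fields
#'   `last_absorbed` (g), `last_evap` (g), `last_noise` (g) and
#'   `last_clamped` (logical) for mass-balance auditing.
#' @export
step_water_balance <- function(state, irrigation_ml, H, T0 = 2,
                               params = evap_params(), process_sd = 0.02,
                               seed = NULL) {
  stopifnot(inherits(state, "sheet_state"), T0 > 0, irrigation_ml >= 0,
            process_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  absorbed <- if (state$W < 0.67) {
    irrigation_ml
  } else {
    min(irrigation_ml, max(0, (state$W_max - state$W) * state$m_GP))
  }
  evap <- if (state$W > 0) {
    state$evap_multiplier *
      gp_evaporation(params, H, state$W, state$m_GP) * T0
  } else {
    0
  }
  noise <- if (process_sd > 0) stats::rnorm(1, 0, process_sd) * state$m_GP else 0
  w_unclamped <- state$W + (absorbed - evap + noise) / state$m_GP
  w_new <- min(max(w_unclamped, 0), state$W_max)
  out <- state
  out$W <- w_new
  out$last_absorbed <- absorbed
  out$last_evap <- evap
  out$last_noise <- noise
  out$last_clamped <- !isTRUE(all.equal(w_new, w_unclamped))
  out
}

#' Piecewise-constant ambient-humidity trajectory
#'
#' Bounded (reflected) Gaussian random walk on the sampling grid, values kept
#' inside the observed ambient range (21--33% by default). With `sd = 0` the
#' series is constant at `start` (default: the range midpoint, 27%).
#'
#' @param duration_h Total duration in hours (> 0).
#' @param T0 Sampling interval in hours (default 2).
#' @param seed Optional integer seed.
#' @param start Starting humidity in percent.
#' @param sd Random-walk step standard deviation in percentage points per
#'   interval (default 1).
#' @param range Length-2 admissible humidity range in percent.
#' @return Numeric vector of length `ceiling(duration_h / T0) + 1` (one value
#'   per grid point, including both endpoints).
#' @export
humidity_trajectory <- function(duration_h, T0 = 2, seed = NULL, start = 27,
                                sd = 1, range = c(21, 33)) {
  stopifnot(duration_h > 0, T0 > 0, sd >= 0,
            start >= range[1], start <= range[2])
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(duration_h / T0) + 1L
  h <- numeric(n)
  h[1] <- start
  if (n > 1) {
    steps <- if (sd > 0) stats::rnorm(n - 1L, 0, sd) else numeric(n - 1L)
    for (k in 2:n) {
      x <- h[k - 1L] + steps[k - 1L]
      # reflect at the bounds
      while (x < range[1] || x > range[2]) {
        if (x < range[1]) x <- 2 * range[1] - x
        if (x > range[2]) x <- 2 * range[2] - x
      }
      h[k] <- x
    }
  }
  h
}
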