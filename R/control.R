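#' Irrigation-controller configuration
#'
#' Settings shared by the discrete PI controller and the quantized-actuation
#' MPC. The controlled plant is modelled as a discrete integrator with
#' zero-order-hold input: one interval of irrigation `I` (mL, = g of
#' solution) raises the water content by `I / T1` g/g, with `T1` identified
#' with the dry sheet mass in gram so that the gain converts mass to g/g.
#'
#' The PI controller is the difference equation
#' `u_k = u_{k-1} + g * (e_k - 0.6 * e_{k-1})` (transfer function
#' `(1 - 0.6 z^-1) / (1 - z^-1)` times the volume gain `g`); the MPC
#' exhaustively searches irrigation sequences over the quantized action set
#' and applies the first action of the best sequence.
#'
#' @param kind `"MPC"` or `"PI"`.
#' @param T0 Sampling interval in hours (default 2).
#' @param T1 Integrator constant in gram (default 45, the dry sheet mass).
#' @param action_set Ordered admissible volumes in mL; default
#'   `{0, 5, ..., 30}` (discrete tank fills of 5--30 mL, plus no fill).
#' @param horizon MPC prediction horizon in steps (1--4; default 3).
#' @param pi_zero Zero of the PI transfer function (default 0.6).
#' @param gain_volume_per_error PI volume gain in mL per g/g (default 45).
#' @param use_feedforward Logical: include the evaporation model as a known
#'   disturbance inside predictions (default TRUE).
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(kind = c("MPC", "PI"), T0 = 2, T1 = 45,
                              action_set = seq(0, 30, by = 5), horizon = 3,
                              pi_zero = 0.6, gain_volume_per_error = 45,
                              use_feedforward = TRUE) {
  kind <- match.arg(kind)
  action_set <- sort(unique(as.numeric(action_set)))
  nz <- action_set[action_set > 0]
  stopifnot(
    T0 > 0, T1 > 0, length(action_set) >= 1,
    all(nz >= 5), all(action_set <= 30),
    horizon >= 1, pi_zero >= 0, gain_volume_per_error > 0
  )
  if (kind == "MPC" && horizon > 4) {
    stop("MPC horizon must be <= 4 (exhaustive enumeration bound)")
  }
  structure(
    list(kind = kind, T0 = T0, T1 = T1, action_set = action_set,
         horizon = as.integer(horizon), pi_zero = pi_zero,
         gain_volume_per_error = gain_volume_per_error,
         use_feedforward = isTRUE(use_feedforward)),
    class = "controller_config"
  )
}

#' @export
print.controller_config <- function(x, ...) {
  cat(sprintf("<controller_config> %s, T0 = %g h, T1 = %g g, actions {%s} mL\n",
              x$kind, x$T0, x$T1, paste(x$action_set, collapse = ", ")))
  if (x$kind == "MPC") {
    cat(sprintf("  horizon %d, evaporation feed-forward %s\n", x$horizon,
                if (x$use_feedforward) "on" else "off"))
  } else {
    cat(sprintf("  zero %g, gain %g mL per g/g\n", x$pi_zero,
                x$gain_volume_per_error))
  }
  invisible(x)
}

#' Control mode: individual or group
#'
#' In individual mode every actuated sheet is measured and controlled on its
#' own. In group mode one command is computed from the mean filtered
#' estimate of the measured sheets (two per group in the reference setup)
#' and applied identically to all actuated sheets (five per group); the
#' unmeasured sheets are thereby open-loop.
#'
#' @param mode `"individual"` or `"group"`.
#' @param measured_sheets Character vector of measured sheet ids.
#' @param actuated_sheets Character vector of actuated sheet ids (must
#'   contain the measured ones).
#' @return An object of class `control_mode`.
#' @export
control_mode <- function(mode = c("individual", "group"),
                         measured_sheets, actuated_sheets = measured_sheets) {
  mode <- match.arg(mode)
  measured_sheets <- as.character(measured_sheets)
  actuated_sheets <- as.character(actuated_sheets)
  stopifnot(length(measured_sheets) >= 1,
            all(measured_sheets %in% actuated_sheets))
  if (mode == "individual" && !setequal(measured_sheets, actuated_sheets)) {
    stop("individual mode requires every actuated sheet to be measured")
  }
  structure(
    list(mode = mode, measured_sheets = measured_sheets,
         actuated_sheets = actuated_sheets),
    class = "control_mode"
  )
}

#' Project a raw volume onto the quantized action set
#'
#' Nearest admissible volume; exact ties resolve toward the smaller volume.
#'
#' @param u Raw volume in mL (vectorised).
#' @param action_set Sorted admissible volumes.
#' @return Elements of `action_set`.
#' @export
#' @examples
#' quantize_action(12.4, seq(0, 30, 5)) # 10
quantize_action <- function(u, action_set = seq(0, 30, by = 5)) {
  action_set <- sort(action_set)
  vapply(u, function(ui) action_set[which.min(abs(action_set - ui))],
         numeric(1))
}

#' One-step internal plant model
#'
#' Deterministic prediction used inside the controllers: integrator
#' `W' = W + I / T1`, optionally minus the modelled evaporation
#' `E(H, W) * T0 / m_GP` as a known disturbance (feed-forward), clamped at 0.
#'
#' @param W Water content, g/g (vectorised).
#' @param I Irrigation volume, mL (vectorised or scalar).
#' @param cfg A [controller_config()].
#' @param H Relative humidity in percent (needed when `params` is given).
#' @param params Optional [evap_params()]; when NULL (default) no
#'   evaporation term is subtracted.
#' @param m_GP Dry mass in gram (defaults to `cfg$T1`).
#' @return Predicted water content, g/g.
#' @export
plant_model_step <- function(W, I, cfg, H = NULL, params = NULL,
                             m_GP = cfg$T1) {
  stopifnot(inherits(cfg, "controller_config"))
  w_new <- W + I / cfg$T1
  if (!is.null(params)) {
    stopifnot(!is.null(H))
    e <- gp_evaporation(params, H, pmax(W, 1e-6), m_GP)
    w_new <- w_new - e * cfg$T0 / m_GP
  }
  pmax(w_new, 0)
}

#' One step of the discrete PI controller
#'
#' Difference equation `u_k = u_{k-1} + g * (e_k - zero * e_{k-1})` on the
#' raw (unquantized) input, clamped to the action range as anti-windup, then
#' projected onto the quantized action set. The raw value must be fed back
#' as `u_prev` at the next step; quantization then acts as an output stage
#' only and does not accumulate in the integrator.
#'
#' @param e_k Current control error `ref - estimate`, g/g.
#' @param e_prev Previous control error, g/g.
#' @param u_prev Previous raw controller output, mL.
#' @param cfg A [controller_config()].
#' @param clamp Logical: clamp the raw output to the action range (default
#'   TRUE; disable to inspect the unclamped difference equation).
#' @return List with `raw` (clamped raw output, mL) and `command` (projected
#'   volume, an element of the action set).
#' @export
#' @examples
#' # unit-step error, unit gain: raw sequence 1, 1.4, 1.8, ...
#' cfg <- controller_config("PI", gain_volume_per_error = 1)
#' pi_step(1, 0, 0, cfg, clamp = FALSE)$raw
pi_step <- function(e_k, e_prev, u_prev, cfg, clamp = TRUE) {
  stopifnot(inherits(cfg, "controller_config"))
  u_raw <- u_prev + cfg$gain_volume_per_error * (e_k - cfg$pi_zero * e_prev)
  if (clamp) {
    u_raw <- min(max(u_raw, min(cfg$action_set)), max(cfg$action_set))
  }
  list(raw = u_raw, command = quantize_action(u_raw, cfg$action_set))
}

# Enumerate action_set^horizon in lexicographic order with the FIRST action
# most significant, so which.min's first-hit rule breaks ties toward the
# smaller first action (then smaller later actions).
action_grid <- function(action_set, horizon) {
  g <- expand.grid(rev(rep(list(action_set), horizon)),
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, rev(seq_len(horizon)), drop = FALSE])
}

#' One step of the quantized-actuation MPC
#'
#' Exhaustively enumerates all irrigation sequences of length `horizon` over
#' the action set, simulates each through the internal plant model (with the
#' evaporation model as feed-forward when enabled), and returns the first
#' action of the sequence minimizing the summed squared tracking error
#' against the reference over the horizon. Ties break toward smaller
#' volumes. Humidity is held at its current value across the horizon.
#'
#' @param W_hat Current filtered water-content estimate, g/g.
#' @param ref_horizon Reference values for the next `horizon` steps, g/g
#'   (recycled from its last value if shorter).
#' @param H Current relative humidity in percent.
#' @param cfg A [controller_config()] with `kind = "MPC"`.
#' @param params An [evap_params()] object (used when
#'   `cfg$use_feedforward`).
#' @param m_GP Dry mass in gram (defaults to `cfg$T1`).
#' @return The chosen volume in mL, with attributes `cost` (optimal cost)
#'   and `sequence` (the full optimal action sequence).
#' @export
mpc_step <- function(W_hat, ref_horizon, H, cfg, params = evap_params(),
                     m_GP = cfg$T1) {
  stopifnot(inherits(cfg, "controller_config"), is.numeric(W_hat),
            length(W_hat) == 1L)
  h <- cfg$horizon
  if (h > 4) stop("horizon too large for exhaustive enumeration (max 4)")
  ref <- rep_len(ref_horizon, h)
  grid <- action_grid(cfg$action_set, h)
  w <- rep(W_hat, nrow(grid))
  cost <- numeric(nrow(grid))
  ff <- if (cfg$use_feedforward) params else NULL
  for (j in seq_len(h)) {
    w <- plant_model_step(w, grid[, j], cfg, H = H, params = ff, m_GP = m_GP)
    cost <- cost + (ref[j] - w)^2
  }
  best <- which.min(cost)
  structure(grid[best, 1], cost = cost[best], sequence = unname(grid[best, ]))
}

#' One group-control step
#'
#' Computes a single irrigation command from the mean of the measured
#' sheets' filtered estimates and returns it for application to every
#' actuated sheet of the group. When no valid (finite) estimate is available
#' this step, the previous command is repeated (hold).
#'
#' @param estimates Numeric vector of filtered estimates of the measured
#'   sheets, g/g (NAs are dropped).
#' @param ref_horizon Reference value(s): scalar for PI, horizon vector for
#'   MPC.
#' @param H Current relative humidity in percent.
#' @param cfg A [controller_config()].
#' @param params An [evap_params()] object.
#' @param m_GP Dry mass in gram.
#' @param pi_state For `kind = "PI"`: list with `e_prev` and `u_prev` (raw).
#' @param prev_command Command to hold when no estimate is valid, mL.
#' @return List with `command` (mL, applied to all actuated sheets),
#'   `mean_estimate`, and the updated `pi_state`.
#' @export
group_step <- function(estimates, ref_horizon, H, cfg,
                       params = evap_params(), m_GP = cfg$T1,
                       pi_state = list(e_prev = 0, u_prev = 0),
                       prev_command = 0) {
  est <- estimates[is.finite(estimates)]
  if (length(est) == 0) {
    return(list(command = prev_command, mean_estimate = NA_real_,
                pi_state = pi_state))
  }
  w_bar <- mean(est)
  if (cfg$kind == "MPC") {
    cmd <- as.numeric(mpc_step(w_bar, ref_horizon, H, cfg, params, m_GP))
  } else {
    e_k <- ref_horizon[1] - w_bar
    st <- pi_step(e_k, pi_state$e_prev, pi_state$u_prev, cfg)
    cmd <- st$command
    pi_state <- list(e_prev = e_k, u_prev = st$raw)
  }
  list(command = cmd, mean_estimate = w_bar, pi_state = pi_state)
}
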