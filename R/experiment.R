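#' Closed-loop test protocol
#'
#' Reference schedule and sampling grid of a closed-loop run. The default
#' reproduces the two-level deficit protocol: reference water content
#' 0.89 g/g for five days, then 0.56 g/g for four days, with a 2 h control
#' interval and twice-daily gravimetric (true-weight) sampling.
#'
#' Gravimetric samplings are offset from midnight by `gravimetric_offset_h`
#' (default 6 h, i.e. at 06:00 and 18:00 of each simulated day) so that a
#' weighing never coincides with the instant at which the reference steps;
#' the metrics then measure regulation quality rather than the unavoidable
#' within-interval transient of a step change.
#'
#' @param reference_schedule Data frame with columns `days` (> 0) and `w`
#'   (reference in g/g, within `[0, 2]`).
#' @param T0 Control interval in hours.
#' @param gravimetric_every_h Gravimetric sampling period in hours
#'   (default 12).
#' @param gravimetric_offset_h Offset of the first gravimetric sampling, h.
#' @return An object of class `gp_protocol`.
#' @export
gp_protocol <- function(reference_schedule = data.frame(days = c(5, 4),
                                                        w = c(0.89, 0.56)),
                        T0 = 2, gravimetric_every_h = 12,
                        gravimetric_offset_h = 6) {
  stopifnot(
    is.data.frame(reference_schedule),
    all(c("days", "w") %in% names(reference_schedule)),
    all(reference_schedule$days > 0),
    all(reference_schedule$w >= 0 & reference_schedule$w <= 2),
    T0 > 0, gravimetric_every_h > 0, gravimetric_offset_h >= 0
  )
  structure(
    list(reference_schedule = reference_schedule, T0 = T0,
         gravimetric_every_h = gravimetric_every_h,
         gravimetric_offset_h = gravimetric_offset_h),
    class = "gp_protocol"
  )
}

#' @export
print.gp_protocol <- function(x, ...) {
  cat("<gp_protocol>\n")
  for (i in seq_len(nrow(x$reference_schedule))) {
    cat(sprintf("  %g days at w = %.2f g/g\n",
                x$reference_schedule$days[i], x$reference_schedule$w[i]))
  }
  cat(sprintf("  T0 = %g h, gravimetric every %g h (offset %g h)\n",
              x$T0, x$gravimetric_every_h, x$gravimetric_offset_h))
  invisible(x)
}

#' Per-step reference series of a protocol
#'
#' @param protocol A [gp_protocol()].
#' @return Numeric vector of references, one per grid point `t = 0, T0,
#'   2*T0, ...` including the final instant.
#' @export
reference_series <- function(protocol) {
  steps_per_phase <- round(protocol$reference_schedule$days * 24 / protocol$T0)
  refs <- rep(protocol$reference_schedule$w, steps_per_phase)
  c(refs, refs[length(refs)]) # value at the terminal grid point
}

#' Run a closed-loop water-content control experiment
#'
#' Simulates the full loop on the control grid: per interval, measure the
#' selected sheets (contact position chosen from the current estimate),
#' Kalman-filter the raw readings, compute irrigation commands (individual
#' or group mode; PI or MPC), actuate, and step every sheet's true water
#' balance. Gravimetric (true-W) snapshots are flagged on the protocol's
#' weighing instants.
#'
#' @param protocol A [gp_protocol()].
#' @param cohort List of [sheet_state()] objects, e.g. from [make_cohort()].
#' @param mode A [control_mode()]; defaults to individual control of every
#'   sheet.
#' @param cfg A [controller_config()].
#' @param params An [evap_params()] object (used by the plant, the filter
#'   and the controllers).
#' @param curves Calibration curves per position, as from
#'   [default_calibration_curves()].
#' @param seed Optional integer seed governing every random draw of the run
#'   (humidity, measurement noise, process noise).
#' @param q Kalman process-noise variance per step, (g/g)^2. The closed-loop
#'   default `0.02^2 + 0.037^2` combines the plant process noise (0.02 g/g)
#'   with the per-step model error induced by the default 10% sheet-to-sheet
#'   evaporation spread (0.1 times the nominal per-step evaporation of about
#'   16.7 g over 45 g dry mass, i.e. 0.037 g/g); for a nominal sheet with no
#'   heterogeneity the bare-filter default `0.02^2` is appropriate.
#' @param process_sd Plant process-noise sd in g/g per step.
#' @param humidity_sd Random-walk step sd of the ambient humidity, percent.
#' @return An object of class `experiment_log`: list with `log` (one row per
#'   grid point and sheet: `t_h`, `sheet_id`, `W_true`, `W_raw`, `W_hat`,
#'   `P`, `position`, `in_range`, `command_mL`, `reference`, `H`,
#'   `gravimetric`, `clamped`) and `meta` (configs and seed).
#' @export
run_experiment <- function(protocol = gp_protocol(), cohort,
                           mode = NULL, cfg = controller_config(),
                           params = evap_params(),
                           curves = default_calibration_curves(),
                           seed = NULL, q = 0.02^2 + 0.037^2,
                           process_sd = 0.02, humidity_sd = 1) {
  stopifnot(inherits(protocol, "gp_protocol"), is.list(cohort),
            length(cohort) >= 1,
            all(vapply(cohort, inherits, TRUE, "sheet_state")))
  ids <- vapply(cohort, `[[`, "", "sheet_id")
  if (anyDuplicated(ids)) stop("duplicate sheet ids in cohort")
  names(cohort) <- ids
  if (is.null(mode)) mode <- control_mode("individual", ids)
  stopifnot(inherits(mode, "control_mode"), inherits(cfg, "controller_config"))
  if (!all(mode$actuated_sheets %in% ids)) {
    stop("control mode references sheets absent from the cohort")
  }
  if (abs(cfg$T0 - protocol$T0) > 1e-9) {
    stop("controller and protocol sampling intervals disagree")
  }
  if (!is.null(seed)) set.seed(seed)

  refs <- reference_series(protocol)
  n_grid <- length(refs) # grid points t = 0 .. duration
  duration_h <- (n_grid - 1) * protocol$T0
  H <- humidity_trajectory(duration_h, protocol$T0, sd = humidity_sd)
  t_h <- (seq_len(n_grid) - 1) * protocol$T0
  grav <- (t_h - protocol$gravimetric_offset_h) %% protocol$gravimetric_every_h == 0 &
    t_h >= protocol$gravimetric_offset_h

  measured <- mode$measured_sheets
  actuated <- mode$actuated_sheets
  filters <- stats::setNames(
    lapply(measured, function(i) kalman_state(q = q, curves = curves)),
    measured
  )
  pos_override <- stats::setNames(rep(NA_integer_, length(measured)), measured)
  # controller bookkeeping: one unit per measured sheet (individual) or one
  # per group (group mode)
  units <- if (mode$mode == "group") list(group = measured) else
    stats::setNames(as.list(measured), measured)
  pi_states <- lapply(units, function(u) list(e_prev = 0, u_prev = 0))
  prev_cmd_unit <- lapply(units, function(u) 0)
  last_cmd <- stats::setNames(rep(0, length(cohort)), ids)

  rows <- vector("list", n_grid)
  for (k in seq_len(n_grid)) {
    # --- predict the filters through the interval that just elapsed
    if (k > 1) {
      for (i in measured) {
        filters[[i]] <- kf_predict(filters[[i]], last_cmd[[i]], H[k - 1],
                                   protocol$T0, cohort[[i]]$m_GP, params)
      }
    }
    # --- measure and update
    meas <- list()
    for (i in measured) {
      pos <- if (!is.na(pos_override[[i]])) {
        pos_override[[i]]
      } else {
        guess <- if (filters[[i]]$initialized) filters[[i]]$w_hat else refs[k]
        select_position(guess)
      }
      curve <- curves[[paste0("p", pos)]]
      s <- simulate_raw_measurement(cohort[[i]]$W, curve,
                                    timestamp = t_h[k], sheet_id = i)
      filters[[i]] <- if (s$in_effective_range) {
        kf_update(filters[[i]], s)
      } else {
        kf_rail_update(filters[[i]], s)
      }
      pos_override[[i]] <- if (s$in_effective_range) NA_integer_ else
        fallback_position(s$raw_water_content, curves)
      meas[[i]] <- s
    }
    # --- control (command applied over the coming interval)
    cmd <- stats::setNames(rep(NA_real_, length(cohort)), ids)
    if (k < n_grid) {
      hsteps <- if (cfg$kind == "MPC") {
        refs[pmin(k + seq_len(cfg$horizon), n_grid)]
      } else {
        refs[k]
      }
      for (u in names(units)) {
        est <- vapply(units[[u]], function(i) {
          if (filters[[i]]$initialized) filters[[i]]$w_hat else NA_real_
        }, numeric(1))
        m_GP_u <- cohort[[units[[u]][1]]]$m_GP
        if (all(is.na(est))) {
          # before the filter has locked on, irrigate open-loop with the
          # feed-forward fill balancing modelled evaporation at the reference
          ff <- gp_evaporation(params, H[k], refs[k], m_GP_u) * protocol$T0
          ff <- min(max(ff, min(cfg$action_set)), max(cfg$action_set))
          # bumpless transfer: park the PI integrator at the feed-forward fill
          st <- list(command = quantize_action(ff, cfg$action_set),
                     pi_state = list(e_prev = 0, u_prev = ff))
        } else {
          st <- group_step(est, hsteps, H[k], cfg, params, m_GP = m_GP_u,
                           pi_state = pi_states[[u]],
                           prev_command = prev_cmd_unit[[u]])
        }
        pi_states[[u]] <- st$pi_state
        prev_cmd_unit[[u]] <- st$command
        targets <- if (mode$mode == "group") actuated else units[[u]]
        cmd[targets] <- st$command
      }
      cmd[is.na(cmd)] <- 0
    }
    rows[[k]] <- data.frame(
      t_h = t_h[k],
      sheet_id = ids,
      W_true = vapply(cohort, `[[`, 0, "W"),
      W_raw = vapply(ids, function(i) {
        if (!is.null(meas[[i]])) meas[[i]]$raw_water_content else NA_real_
      }, numeric(1)),
      W_hat = vapply(ids, function(i) {
        if (i %in% measured && filters[[i]]$initialized)
          filters[[i]]$w_hat else NA_real_
      }, numeric(1)),
      P = vapply(ids, function(i) {
        if (i %in% measured && filters[[i]]$initialized)
          filters[[i]]$p else NA_real_
      }, numeric(1)),
      position = vapply(ids, function(i) {
        if (!is.null(meas[[i]])) meas[[i]]$position else NA_integer_
      }, integer(1)),
      in_range = vapply(ids, function(i) {
        if (!is.null(meas[[i]])) meas[[i]]$in_effective_range else NA
      }, logical(1)),
      command_mL = unname(cmd),
      reference = refs[k],
      H = H[k],
      gravimetric = grav[k],
      clamped = NA,
      row.names = NULL
    )
    # --- actuate and step the true plants
    if (k < n_grid) {
      clamped <- logical(length(cohort))
      for (j in seq_along(cohort)) {
        cohort[[j]] <- step_water_balance(cohort[[j]], cmd[[ids[j]]], H[k],
                                          protocol$T0, params,
                                          process_sd = process_sd)
        clamped[j] <- cohort[[j]]$last_clamped
      }
      rows[[k]]$clamped <- clamped
      last_cmd <- cmd
    }
  }
  structure(
    list(
      log = do.call(rbind, rows),
      meta = list(protocol = protocol, mode = mode, cfg = cfg,
                  params = params, seed = seed, q = q,
                  process_sd = process_sd, humidity_sd = humidity_sd)
    ),
    class = "experiment_log"
  )
}

#' @export
print.experiment_log <- function(x, ...) {
  cat(sprintf(
    "<experiment_log> %d sheets x %d grid points (%s, %s control), T0 = %g h\n",
    length(unique(x$log$sheet_id)), length(unique(x$log$t_h)),
    x$meta$cfg$kind, x$meta$mode$mode, x$meta$protocol$T0
  ))
  invisible(x)
}

#' Measurement-system accuracy of a run
#'
#' Maximal absolute deviation of the filtered estimate from the true water
#' content over the control steps at which the *true* content lay inside the
#' effective range of the contact position measured (the range over which
#' the measurement system claims accuracy).
#'
#' @param x An `experiment_log` from [run_experiment()].
#' @param curves The calibration curves used (for the effective ranges).
#' @return Maximal in-range absolute estimate error, g/g (NA if no step
#'   qualified).
#' @export
filter_accuracy <- function(x, curves = default_calibration_curves()) {
  stopifnot(inherits(x, "experiment_log"))
  d <- x$log[!is.na(x$log$position) & !is.na(x$log$W_hat), , drop = FALSE]
  if (nrow(d) == 0) return(NA_real_)
  lo <- vapply(d$position, function(p) curves[[paste0("p", p)]]$effective_range[1], 0)
  hi <- vapply(d$position, function(p) curves[[paste0("p", p)]]$effective_range[2], 0)
  ok <- d$W_true >= lo & d$W_true <= hi
  if (!any(ok)) return(NA_real_)
  max(abs(d$W_hat[ok] - d$W_true[ok]))
}

#' Control deviation
#'
#' `e = w - W_grav`: reference minus gravimetrically measured (true) water
#' content.
#'
#' @param w Reference, g/g (vectorised).
#' @param W_grav Gravimetric water content, g/g.
#' @return Deviation in g/g.
#' @export
control_deviation <- function(w, W_grav) {
  w - W_grav
}

#' Integral of squared control error
#'
#' Trapezoidal approximation of `A_quad = integral of e^2 dt` on a uniform
#' time grid. The reported unit is (g/g)^2 * hour.
#'
#' @param e_series Deviation series, g/g.
#' @param dt Grid spacing in hours.
#' @return The integral, (g/g)^2 h.
#' @export
integral_squared_error <- function(e_series, dt) {
  if (length(e_series) == 0) stop("empty deviation series")
  stopifnot(dt > 0, all(is.finite(e_series)))
  if (length(e_series) == 1) return(0)
  t <- (seq_along(e_series) - 1) * dt
  pracma::trapz(t, e_series^2)
}

#' Summarize control quality of a run
#'
#' Computes the deviation `e = w - W_true` at the gravimetric sampling
#' instants and reports, per sheet: maximal `|e|`, the integral of squared
#' error (trapezoid over the gravimetric grid, (g/g)^2 h), median, mean and
#' standard deviation of `e`. For group-control runs a group summary
#' (median, mean, sd over all sheets of the group) is computed over a
#' window of the run; the default window covers seven gravimetric instants
#' of the first reference phase after an initial settling period
#' (`t` from 30 h to 102 h), matching the reporting convention of seven
#' weighings per plant.
#'
#' @param x An `experiment_log` from [run_experiment()].
#' @param group_window_h Length-2 time window (hours) for the group
#'   summary.
#' @return An object of class `metrics_report`: list with `per_sheet` and
#'   (for group runs) `group` data frames.
#' @export
summarize_experiment <- function(x, group_window_h = c(30, 102)) {
  stopifnot(inherits(x, "experiment_log"))
  g <- x$log[x$log$gravimetric, , drop = FALSE]
  if (nrow(g) == 0) stop("log contains no gravimetric instants")
  g$e <- control_deviation(g$reference, g$W_true)
  dt <- x$meta$protocol$gravimetric_every_h
  per_sheet <- do.call(rbind, lapply(split(g, g$sheet_id), function(d) {
    d <- d[order(d$t_h), , drop = FALSE]
    data.frame(
      sheet_id = d$sheet_id[1],
      n = nrow(d),
      max_abs_e = max(abs(d$e)),
      A_quad = integral_squared_error(d$e, dt),
      median_e = stats::median(d$e),
      mean_e = mean(d$e),
      sd_e = stats::sd(d$e),
      row.names = NULL
    )
  }))
  out <- list(per_sheet = per_sheet)
  win <- g[g$t_h >= group_window_h[1] & g$t_h <= group_window_h[2], ]
  if (x$meta$mode$mode == "group" && nrow(win) > 0) {
    out$group <- data.frame(
      n_sheets = length(unique(win$sheet_id)),
      n_measurements = nrow(win),
      median_e = stats::median(win$e),
      mean_e = mean(win$e),
      sd_e = stats::sd(win$e),
      max_abs_e = max(abs(win$e))
    )
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> per sheet (deviations at gravimetric instants, g/g):\n")
  print(x$per_sheet, row.names = FALSE, digits = 3)
  if (!is.null(x$group)) {
    cat("group summary:\n")
    print(x$group, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
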