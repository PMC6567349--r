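#' Default run configuration
#'
#' Nested list describing a complete reproducible closed-loop run: seed,
#' circuit constants, calibration curves, evaporation coefficients, cohort
#' settings, controller and mode per group, and the protocol. The structure
#' round-trips through YAML ([write_run_config()] / [read_run_config()])
#' and is validated by [validate_run_config()].
#'
#' @param seed Integer master seed.
#' @param n_sheets Cohort size.
#' @param kind Controller kind, `"MPC"` or `"PI"`.
#' @param mode `"individual"` or `"group"`.
#' @return A named list (class `run_config`).
#' @export
default_run_config <- function(seed = 1, n_sheets = 5,
                               kind = "MPC", mode = "group") {
  cp <- circuit_params()
  curves <- default_calibration_curves(cp)
  ep <- evap_params()
  structure(list(
    seed = as.integer(seed),
    circuit = list(
      series_capacitance_F = cp$series_capacitance,
      discharge_duration_s = cp$discharge_duration,
      initial_charge_C = cp$initial_charge,
      current_accuracy_A = cp$current_accuracy,
      sampling_frequency_Hz = cp$sampling_frequency
    ),
    curves = lapply(curves, function(cu) list(
      position = cu$position, slope = cu$slope, intercept = cu$intercept,
      effective_range = cu$effective_range
    )),
    evaporation = list(c1 = ep$c1, c2 = ep$c2, c3 = ep$c3, c4 = ep$c4,
                       rate_scale = ep$rate_scale,
                       uptake_g_per_h = ep$uptake_g_per_h),
    cohort = list(n = as.integer(n_sheets), initial_w = 0.89, m_GP = 45,
                  wmax_range = c(1.78, 2.00), sdlog = 0.1),
    controller = list(kind = kind, T0 = 2, T1 = 45,
                      action_set = seq(0, 30, 5), horizon = 3,
                      pi_zero = 0.6, gain_volume_per_error = 45,
                      use_feedforward = TRUE),
    mode = list(mode = mode,
                measured_sheets = if (mode == "group") c("sheet1", "sheet2")
                                  else paste0("sheet", seq_len(n_sheets)),
                actuated_sheets = paste0("sheet", seq_len(n_sheets))),
    protocol = list(phases = list(list(days = 5, w = 0.89),
                                  list(days = 4, w = 0.56)),
                    T0 = 2, gravimetric_every_h = 12,
                    gravimetric_offset_h = 6),
    noise = list(q = 0.02^2, process_sd = 0.02, humidity_sd = 1)
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks presence and basic sanity of every required field; errors name the
#' offending field.
#'
#' @param config A list as produced by [default_run_config()] or read from
#'   YAML.
#' @return The config, invisibly, on success.
#' @export
validate_run_config <- function(config) {
  need <- function(path, check = NULL) {
    node <- config
    for (p in path) {
      if (!is.list(node) || is.null(node[[p]])) {
        stop("run config: missing field `", paste(path, collapse = "$"), "`",
             call. = FALSE)
      }
      node <- node[[p]]
    }
    if (!is.null(check) && !isTRUE(check(node))) {
      stop("run config: invalid value for `", paste(path, collapse = "$"),
           "`", call. = FALSE)
    }
    node
  }
  need("seed", function(x) is.numeric(x) && length(x) == 1)
  need(c("evaporation", "c1"))
  need(c("evaporation", "c2"))
  need(c("evaporation", "c3"))
  need(c("evaporation", "c4"))
  need(c("evaporation", "rate_scale"), function(x) x > 0)
  need(c("cohort", "n"), function(x) x >= 1)
  need(c("cohort", "initial_w"), function(x) x >= 0)
  need(c("controller", "kind"), function(x) x %in% c("MPC", "PI"))
  need(c("controller", "action_set"), function(x) length(x) >= 1)
  need(c("mode", "mode"), function(x) x %in% c("individual", "group"))
  need(c("mode", "measured_sheets"), function(x) length(x) >= 1)
  need(c("protocol", "phases"), function(x) length(x) >= 1)
  for (cv in need("curves")) {
    if (is.null(cv$slope) || is.null(cv$intercept) ||
        is.null(cv$effective_range)) {
      stop("run config: each curve needs `slope`, `intercept`, `effective_range`",
           call. = FALSE)
    }
  }
  invisible(config)
}

#' Write / read a run configuration as YAML
#'
#' @param config A run-config list.
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the validated config.
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  config <- yaml::read_yaml(path)
  validate_run_config(config)
  structure(config, class = "run_config")
}

# Build live objects from a (validated) config list.
objects_from_config <- function(config) {
  curves <- lapply(config$curves, function(cv) {
    calibration_curve(cv$position, cv$slope, cv$intercept,
                      as.numeric(cv$effective_range))
  })
  names(curves) <- paste0("p", vapply(curves, `[[`, 0L, "position"))
  ep <- config$evaporation
  ct <- config$controller
  sched <- do.call(rbind, lapply(config$protocol$phases, function(ph) {
    data.frame(days = ph$days, w = ph$w)
  }))
  list(
    curves = curves,
    params = evap_params(ep$c1, ep$c2, ep$c3, ep$c4,
                         rate_scale = ep$rate_scale,
                         uptake_g_per_h = ep$uptake_g_per_h),
    cfg = controller_config(ct$kind, T0 = ct$T0, T1 = ct$T1,
                            action_set = unlist(ct$action_set),
                            horizon = ct$horizon, pi_zero = ct$pi_zero,
                            gain_volume_per_error = ct$gain_volume_per_error,
                            use_feedforward = ct$use_feedforward),
    mode = control_mode(config$mode$mode,
                        unlist(config$mode$measured_sheets),
                        unlist(config$mode$actuated_sheets)),
    protocol = gp_protocol(sched, T0 = config$protocol$T0,
                           gravimetric_every_h = config$protocol$gravimetric_every_h,
                           gravimetric_offset_h = config$protocol$gravimetric_offset_h)
  )
}

#' Run a configured closed-loop simulation and write its artifacts
#'
#' Reads and validates a YAML run config, builds the cohort and controllers,
#' runs [run_experiment()], and writes `log.csv` (the tidy experiment log),
#' `metrics.csv` (per-sheet metrics), `group_metrics.csv` (group runs only)
#' and `config_echo.yaml` into `out_dir`.
#'
#' @param config_path Path to a YAML run config.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the written file paths.
#' @export
cli_simulate <- function(config_path, out_dir = ".") {
  config <- read_run_config(config_path)
  obj <- objects_from_config(config)
  co <- config$cohort
  set.seed(config$seed)
  cohort <- make_cohort(co$n, initial_w = co$initial_w, m_GP = co$m_GP,
                        wmax_range = unlist(co$wmax_range), sdlog = co$sdlog)
  log <- run_experiment(obj$protocol, cohort, obj$mode, obj$cfg, obj$params,
                        obj$curves, seed = config$seed,
                        q = config$noise$q,
                        process_sd = config$noise$process_sd,
                        humidity_sd = config$noise$humidity_sd)
  metrics <- summarize_experiment(log)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    log = file.path(out_dir, "log.csv"),
    metrics = file.path(out_dir, "metrics.csv"),
    config_echo = file.path(out_dir, "config_echo.yaml")
  )
  utils::write.csv(log$log, paths$log, row.names = FALSE)
  utils::write.csv(metrics$per_sheet, paths$metrics, row.names = FALSE)
  if (!is.null(metrics$group)) {
    paths$group_metrics <- file.path(out_dir, "group_metrics.csv")
    utils::write.csv(metrics$group, paths$group_metrics, row.names = FALSE)
  }
  yaml::write_yaml(unclass(config), paths$config_echo)
  invisible(paths)
}

#' Fit a calibration curve from a CSV of charge/gravimetric pairs
#'
#' Reads calibration points (columns `charge_C`, `water_g_per_g`, and
#' optionally `position`), fits the logarithmic characteristic curve for one
#' position, and writes the fitted curve as a YAML config fragment mergeable
#' into a run config.
#'
#' @param points_csv Path to the CSV of calibration points.
#' @param position Contact position to fit (rows with a `position` column
#'   are filtered to it).
#' @param out_yaml Output path for the curve fragment (default: alongside
#'   the input).
#' @return The fitted [calibration_curve()], invisibly.
#' @export
cli_calibrate <- function(points_csv, position,
                          out_yaml = sub("\\.csv$", "_curve.yaml", points_csv)) {
  if (!file.exists(points_csv)) stop("points file not found: ", points_csv)
  points <- utils::read.csv(points_csv)
  if (nrow(points) == 0) stop("empty calibration file: ", points_csv)
  if (!all(c("charge_C", "water_g_per_g") %in% names(points))) {
    stop("calibration CSV needs columns `charge_C` and `water_g_per_g`")
  }
  bad <- which(!is.finite(points$charge_C) | !is.finite(points$water_g_per_g) |
                 points$charge_C <= 0)
  if (length(bad)) {
    stop("unparseable or invalid calibration rows (line ",
         paste(bad + 1L, collapse = ", "), " of ", points_csv, ")")
  }
  if ("position" %in% names(points)) {
    points <- points[points$position == as.integer(position), , drop = FALSE]
    if (nrow(points) == 0) stop("no rows for position ", position)
  }
  curve <- fit_calibration(points, position)
  fit <- attr(curve, "fit")
  yaml::write_yaml(list(curve = list(
    position = curve$position, slope = curve$slope,
    intercept = curve$intercept, effective_range = curve$effective_range,
    fit = list(n = fit$n, sigma = fit$sigma,
               max_abs_residual = fit$max_abs_residual,
               r_squared = fit$r_squared)
  )), out_yaml)
  invisible(curve)
}

#' Recompute metrics tables from an experiment log CSV
#'
#' Rebuilds the per-sheet control-quality table (maximal deviation and
#' integral of squared error) and the pooled median/mean/sd table from a
#' `log.csv` written by [cli_simulate()].
#'
#' @param log_csv Path to the log CSV.
#' @param out_dir Optional output directory; when given, `report_max.csv`
#'   and `report_stats.csv` are written there.
#' @return List with `max_table` and `stats_table` data frames.
#' @export
cli_report <- function(log_csv, out_dir = NULL) {
  if (!file.exists(log_csv)) stop("log file not found: ", log_csv)
  log <- utils::read.csv(log_csv)
  need <- c("t_h", "sheet_id", "W_true", "reference", "gravimetric")
  if (!all(need %in% names(log))) {
    stop("incomplete log: needs columns ", paste(need, collapse = ", "))
  }
  g <- log[as.logical(log$gravimetric), , drop = FALSE]
  if (nrow(g) == 0) stop("incomplete log: no gravimetric instants")
  g$e <- control_deviation(g$reference, g$W_true)
  dts <- unique(diff(sort(unique(g$t_h))))
  dt <- if (length(dts)) dts[1] else 12
  max_table <- do.call(rbind, lapply(split(g, g$sheet_id), function(d) {
    d <- d[order(d$t_h), ]
    data.frame(sheet_id = d$sheet_id[1],
               max_abs_deviation = max(abs(d$e)),
               integral_squared_error = integral_squared_error(d$e, dt),
               row.names = NULL)
  }))
  stats_table <- data.frame(
    n = nrow(g),
    median_e = stats::median(g$e),
    mean_e = mean(g$e),
    sd_e = stats::sd(g$e)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(max_table, file.path(out_dir, "report_max.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_table, file.path(out_dir, "report_stats.csv"),
                     row.names = FALSE)
  }
  list(max_table = max_table, stats_table = stats_table)
}
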