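#' Scalar Kalman-filter state for one sheet
#'
#' Filtered water-content estimate with variance, process-noise setting and
#' the band-based measurement-noise policy. The filter predicts with the
#' water-balance model (irrigation in, modelled evaporation out) and corrects
#' with raw calibrated measurements; out-of-range measurements are skipped
#' (predict-only steps), which is also how unmeasured sampling slots are
#' handled.
#'
#' The filter starts uninitialized: the first in-range raw measurement
#' becomes the initial estimate, with initial variance equal to that
#' measurement's band variance.
#'
#' @param q Process-noise variance per predict step, (g/g)^2. Default
#'   `0.02^2`, matching the default plant process noise.
#' @param curves List of calibration curves (as from
#'   [default_calibration_curves()]) supplying the band-to-variance rule.
#' @param w_hat,p Optional explicit initial estimate and variance; when both
#'   are given the filter starts initialized.
#' @return An object of class `kalman_state`.
#' @export
kalman_state <- function(q = 0.02^2, curves = default_calibration_curves(),
                         w_hat = NA_real_, p = NA_real_) {
  stopifnot(q >= 0, is.list(curves))
  initialized <- is.finite(w_hat) && is.finite(p)
  if (initialized) stopifnot(p >= 0)
  structure(
    list(w_hat = w_hat, p = p, q = q, curves = curves,
         initialized = initialized),
    class = "kalman_state"
  )
}

#' @export
print.kalman_state <- function(x, ...) {
  if (x$initialized) {
    cat(sprintf("<kalman_state> W_hat = %.4f g/g, P = %.5f, q = %.5f\n",
                x$w_hat, x$p, x$q))
  } else {
    cat(sprintf("<kalman_state> uninitialized, q = %.5f\n", x$q))
  }
  invisible(x)
}

#' Band-based measurement variance
#'
#' Measurement-noise variance for a raw reading: `r = (accuracy / 2)^2` of
#' the band containing the value, using the band table of the curve the
#' reading was taken with.
#'
#' @param curve A [calibration_curve()].
#' @param w Water-content value, g/g (vectorised).
#' @return Variance in (g/g)^2.
#' @export
measurement_variance <- function(curve, w) {
  stopifnot(inherits(curve, "calibration_curve"))
  (band_at(curve$bands, w)$accuracy / 2)^2
}

#' Kalman prediction through the water-balance model
#'
#' `W_hat' = W_hat + (I - E(H, W_hat) * T0) / m_GP` (clamped at 0) and
#' `P' = P + q`. The evaporation model is evaluated at the current estimate
#' with a unit state-transition Jacobian; the weak logarithmic dependence of
#' the evaporation rate on W makes the neglected Jacobian correction
#' second-order at these magnitudes. An uninitialized filter passes through
#' unchanged.
#'
#' @param ks A [kalman_state()].
#' @param irrigation_ml Irrigation applied over the interval, mL.
#' @param H Relative humidity in percent.
#' @param T0 Interval length in hours (default 2).
#' @param m_GP Dry mass in gram (default 45).
#' @param params An [evap_params()] object.
#' @return The predicted [kalman_state()].
#' @export
kf_predict <- function(ks, irrigation_ml, H, T0 = 2, m_GP = 45,
                       params = evap_params()) {
  stopifnot(inherits(ks, "kalman_state"))
  if (!ks$initialized) return(ks)
  e <- if (ks$w_hat > 0) gp_evaporation(params, H, ks$w_hat, m_GP) else 0
  ks$w_hat <- max(0, ks$w_hat + (irrigation_ml - e * T0) / m_GP)
  ks$p <- ks$p + ks$q
  ks
}

#' Kalman measurement update
#'
#' Standard scalar update with gain `K = P / (P + r)`:
#' `W_hat' = W_hat + K * (raw - W_hat)`, `P' = (1 - K) * P`. Measurements
#' flagged out of the effective range are skipped and the state is returned
#' unchanged (the step stays predict-only). The first in-range measurement
#' initializes the filter.
#'
#' @param ks A [kalman_state()].
#' @param measurement A one-row `measurement_sample` from
#'   [simulate_raw_measurement()] (needs `raw_water_content`,
#'   `in_effective_range` and `position`).
#' @return The updated [kalman_state()].
#' @export
kf_update <- function(ks, measurement) {
  stopifnot(inherits(ks, "kalman_state"),
            all(c("raw_water_content", "in_effective_range", "position") %in%
                  names(measurement)))
  if (!isTRUE(measurement$in_effective_range[1])) return(ks)
  raw <- measurement$raw_water_content[1]
  curve <- ks$curves[[paste0("p", measurement$position[1])]]
  if (is.null(curve)) stop("no calibration curve for position ",
                           measurement$position[1])
  r <- measurement_variance(curve, raw)
  if (!ks$initialized) {
    ks$w_hat <- raw
    ks$p <- r
    ks$initialized <- TRUE
    return(ks)
  }
  k <- ks$p / (ks$p + r)
  ks$w_hat <- ks$w_hat + k * (raw - ks$w_hat)
  ks$p <- (1 - k) * ks$p
  ks
}

#' Censored (rail) update from an out-of-range reading
#'
#' An out-of-range reading is rejected by [kf_update()], but it still
#' carries one-sided information: a reading below the effective range says
#' the sheet is drier than the lower range limit, a reading above says it is
#' wetter than the upper limit. When the current estimate sits on the wrong
#' side of that limit, this update treats the reading as censored at the
#' range boundary and applies a standard scalar update toward the boundary,
#' with the measurement variance of the band at the boundary. When the
#' estimate already agrees with the censoring side (or the filter is
#' uninitialized, or the reading was in range) the state is returned
#' unchanged.
#'
#' Without this, an estimate stranded on the wrong side of the dead zone
#' between the two effective ranges would never be corrected and the control
#' loop would stay open indefinitely.
#'
#' @param ks A [kalman_state()].
#' @param measurement A one-row `measurement_sample`.
#' @return The updated [kalman_state()].
#' @export
kf_rail_update <- function(ks, measurement) {
  stopifnot(inherits(ks, "kalman_state"))
  if (!ks$initialized || isTRUE(measurement$in_effective_range[1])) return(ks)
  curve <- ks$curves[[paste0("p", measurement$position[1])]]
  if (is.null(curve)) stop("no calibration curve for position ",
                           measurement$position[1])
  raw <- measurement$raw_water_content[1]
  rng <- curve$effective_range
  bound <- if (raw < rng[1]) rng[1] else if (raw > rng[2]) rng[2] else
    return(ks)
  informative <- (raw < rng[1] && ks$w_hat > bound) ||
    (raw > rng[2] && ks$w_hat < bound)
  if (!informative) return(ks)
  r <- measurement_variance(curve, bound)
  k <- ks$p / (ks$p + r)
  ks$w_hat <- ks$w_hat + k * (bound - ks$w_hat)
  ks$p <- (1 - k) * ks$p
  ks
}

#' Filter an aligned series of raw measurements
#'
#' Runs alternating predict/update over series aligned on the sampling grid.
#' Rows of `raw` with `NA` raw value (slots where the sheet was not measured)
#' and out-of-range measurements both result in predict-only steps.
#'
#' At grid point `k` the filter first predicts from `k - 1` using
#' `irrigation[k - 1]` and `H[k - 1]` (the command and humidity that acted
#' over the preceding interval), then updates with the measurement at `k`.
#'
#' @param raw Data frame of measurement samples (one row per grid point;
#'   columns `raw_water_content`, `in_effective_range`, `position`).
#' @param irrigation Numeric vector of irrigation commands, mL, same length
#'   (the value at the last grid point is unused).
#' @param H Humidity series in percent, same length.
#' @param T0 Interval in hours.
#' @param m_GP Dry mass in gram.
#' @param params An [evap_params()] object.
#' @param ks Initial [kalman_state()].
#' @return Data frame with columns `w_hat` and `p` (NA before the filter has
#'   been initialized by a first in-range measurement).
#' @export
filter_series <- function(raw, irrigation, H, T0 = 2, m_GP = 45,
                          params = evap_params(), ks = kalman_state()) {
  n <- nrow(raw)
  if (length(irrigation) != n || length(H) != n) {
    stop("`raw`, `irrigation` and `H` must be aligned (equal lengths)")
  }
  w_hat <- p <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (k > 1) {
      ks <- kf_predict(ks, irrigation[k - 1], H[k - 1], T0, m_GP, params)
    }
    if (!is.na(raw$raw_water_content[k])) {
      ks <- kf_update(ks, raw[k, , drop = FALSE])
    }
    if (ks$initialized) {
      w_hat[k] <- ks$w_hat
      p[k] <- ks$p
    }
  }
  data.frame(w_hat = w_hat, p = p)
}
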