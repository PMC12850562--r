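# RF-safety and calibration arithmetic: SAR from MR thermometry, total
# power limits from peak 10 g SAR, sinusoidal B1+ calibration, and Larmor
# frequency bookkeeping.

#' SAR from MR thermometry
#'
#' `SAR = cp * dT / dt`, elementwise for temperature-rise maps, normalized
#' by the incident time-averaged power when `incident_power` is given.
#' Small negative temperature rises are tolerated as thermometry noise;
#' values below -0.5 K are flagged with a warning.
#'
#' @param delta_T temperature rise in K (scalar or array). A spatially
#'   uniform drift offset (oil-reference reading) can be supplied via
#'   `drift_offset` and is subtracted first.
#' @param cp specific heat capacity in J/kg/K (phantom material: 3500).
#' @param delta_t heating duration in s (600 for a 10-min heating block).
#' @param incident_power time-averaged input power in W; if `NULL` the
#'   unnormalized SAR (W/kg) is returned.
#' @param drift_offset scalar drift correction in K (default 0).
#' @return SAR in W/kg, or W/kg per W input if `incident_power` is given.
#' @export
sar_from_thermometry <- function(delta_T, cp = 3500, delta_t = 600,
                                 incident_power = NULL, drift_offset = 0) {
  if (cp <= 0 || delta_t <= 0) stop("cp and delta_t must be positive")
  dT <- delta_T - drift_offset
  if (any(dT < -0.5)) {
    warning("temperature decrease below -0.5 K; check drift correction")
  }
  sar <- cp * dT / delta_t
  if (!is.null(incident_power)) {
    if (incident_power <= 0) stop("incident_power must be positive")
    sar <- sar / incident_power
  }
  sar
}

#' Total power limit from peak 10 g SAR values
#'
#' Divides the permissible SAR cap (20 W/kg in first-level controlled mode)
#' by the worst-case (maximum) peak 10 g SAR per watt across the body
#' models, rounded to the nearest watt. The worst case governs: the limit
#' is monotone non-increasing in every peak SAR value.
#'
#' @param peak_sar_per_watt numeric vector of peak 10 g SAR values in
#'   W/kg per W input power, one per body model.
#' @param sar_cap permissible SAR in W/kg (default 20, first-level mode).
#' @param round_watt round the limit to the nearest watt (default TRUE).
#' @return total power limit in W.
#' @examples
#' total_power_limit(c(0.10, 0.16, 0.07))  # sodium transmit: 125 W
#' total_power_limit(c(0.48, 0.41, 0.43))  # proton transmit: 42 W
#' @export
total_power_limit <- function(peak_sar_per_watt, sar_cap = 20,
                              round_watt = TRUE) {
  if (length(peak_sar_per_watt) == 0) stop("no peak SAR values supplied")
  if (any(peak_sar_per_watt <= 0) || sar_cap <= 0) {
    stop("SAR values and cap must be positive")
  }
  lim <- sar_cap / max(peak_sar_per_watt)
  if (round_watt) round(lim) else lim
}

#' Sinusoidal B1+ calibration fit
#'
#' Fits `S(V) = S0 * |sin(kappa * V)|` to gradient-echo signal magnitudes
#' acquired over a series of reference voltages (e.g. 100-500 V in 50 V
#' steps), returning the flip-angle-per-volt constant `kappa` (rad/V).
#' Initialization places the 90 degree flip at the voltage of maximum
#' signal; a coarse grid search over `kappa in [kappa0/4, 4 kappa0]`
#' precedes local refinement, since the |sin| model has local minima.
#'
#' @param voltages reference voltages in V (>= 3 distinct values).
#' @param signals measured signal magnitudes (same length).
#' @return list with `kappa` (rad/V), `S0`, `rss`, `converged`.
#' @export
fit_b1_sinusoidal <- function(voltages, signals) {
  if (length(unique(voltages)) < 3) stop("need at least 3 distinct voltages")
  if (length(voltages) != length(signals)) stop("length mismatch")
  if (max(signals) - min(signals) <= 0) {
    return(list(kappa = NA_real_, S0 = NA_real_, rss = NA_real_,
                converged = FALSE))
  }
  k0 <- (pi / 2) / voltages[which.max(signals)]
  kgrid <- seq(k0 / 4, 4 * k0, length.out = 400)
  rss_of <- function(k) {
    m <- abs(sin(k * voltages))
    s0 <- sum(signals * m) / sum(m^2)
    sum((signals - s0 * m)^2)
  }
  kbest <- kgrid[which.min(vapply(kgrid, rss_of, numeric(1)))]
  s0best <- {
    m <- abs(sin(kbest * voltages))
    sum(signals * m) / sum(m^2)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(signals ~ S0 * abs(sin(kappa * voltages)),
                      start = list(S0 = s0best, kappa = kbest),
                      lower = c(S0 = 0, kappa = k0 / 8),
                      upper = c(S0 = Inf, kappa = 8 * k0)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(kappa = kbest, S0 = s0best, rss = rss_of(kbest),
                converged = FALSE))
  }
  p <- stats::coef(fit)
  list(kappa = unname(p["kappa"]), S0 = unname(p["S0"]),
       rss = sum(stats::resid(fit)^2), converged = TRUE)
}

#' Larmor frequency
#'
#' `f = gamma * B0`. The sodium gyromagnetic ratio is 11.26 MHz/T, giving
#' 118 MHz at 10.5 T; protons (42.58 MHz/T) resonate at 447 MHz.
#'
#' @param gamma gyromagnetic ratio in MHz/T.
#' @param b0 static field in T (>= 0).
#' @param round_mhz round to the nearest MHz for display (default FALSE).
#' @return frequency in MHz.
#' @export
larmor_frequency <- function(gamma, b0, round_mhz = FALSE) {
  if (b0 < 0) stop("b0 must be >= 0")
  f <- gamma * b0
  if (round_mhz) round(f) else f
}

#' Gyromagnetic ratios (MHz/T) for the supported nuclei
#' @return named numeric vector.
#' @export
gyromagnetic_ratios <- function() c("23Na" = 11.26, "1H" = 42.58)
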