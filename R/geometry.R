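#' Probe geometry for the dual-transducer multigate Doppler device
#'
#' Describes the fixed dual-transducer probe: two unfocused apertures mounted
#' in a rigid casing at a fixed half-angle to the casing normal, interrogating
#' a common set of equally spaced range gates.
#'
#' @param f0 Carrier frequency in Hz. Default 4 MHz.
#' @param half_angle_deg Fixed half-angle between each transducer beam and the
#'   casing bisector, degrees. The two beams sit at `-half_angle_deg` and
#'   `+half_angle_deg`. Default 30.
#' @param n_gates Number of depth gates. Default 32.
#' @param gate_depth_min_mm,gate_depth_max_mm Depth span of the gate centres in
#'   mm from the skin. Defaults 8 and 45.
#' @param prf Pulse repetition frequency in Hz. Default 15000, which respects
#'   the range-ambiguity bound at 45 mm (`c/(2 z_max)` = 17.1 kHz) and keeps
#'   carotid systolic velocities below the Nyquist velocity.
#' @param c_sound Speed of sound in tissue, m/s. Default 1540.
#' @param aperture_mm Aperture dimensions, metadata only. Default `c(30, 6)`.
#'
#' @return An object of class `probe_geometry` (a validated list).
#' @examples
#' geom <- probe_geometry()
#' gate_layout(geom)
#' @export
probe_geometry <- function(f0 = 4e6, half_angle_deg = 30, n_gates = 32,
                           gate_depth_min_mm = 8, gate_depth_max_mm = 45,
                           prf = 15000, c_sound = 1540,
                           aperture_mm = c(30, 6)) {
  if (n_gates < 2) stop_config("`n_gates` must be at least 2")
  if (gate_depth_min_mm <= 0 || gate_depth_max_mm <= gate_depth_min_mm)
    stop_config("gate depth span must satisfy 0 < min < max")
  if (f0 <= 0 || prf <= 0 || c_sound <= 0)
    stop_config("f0, prf and c_sound must be positive")
  prf_max <- c_sound / (2 * gate_depth_max_mm / 1000)
  if (prf > prf_max)
    stop_config(sprintf(
      "prf %.0f Hz violates the range-ambiguity bound %.0f Hz at %.0f mm",
      prf, prf_max, gate_depth_max_mm))
  if (half_angle_deg <= 0 || half_angle_deg >= 90)
    stop_config("`half_angle_deg` must be in (0, 90)")
  structure(
    list(f0 = f0, half_angle_deg = half_angle_deg, n_gates = as.integer(n_gates),
         gate_depth_min_mm = gate_depth_min_mm, gate_depth_max_mm = gate_depth_max_mm,
         prf = prf, c_sound = c_sound, aperture_mm = aperture_mm),
    class = "probe_geometry")
}

#' Vessel model sampled by the gates
#'
#' A straight cylindrical vessel with a blunt (power-law) velocity profile:
#' `v(r) = v_centre * (1 - (r/R)^bluntness)`.
#'
#' @param center_depth_mm Depth of the vessel axis in mm. Default 22 (typical
#'   porcine common carotid depth).
#' @param diameter_mm Lumen diameter in mm. Default 5.
#' @param inclination_deg Angle between the flow axis and the plane normal to
#'   the probe-casing bisector, degrees, signed. Default 0.
#' @param profile_bluntness Profile exponent; 2 is parabolic (Poiseuille),
#'   larger is blunter. Default 4.
#' @return An object of class `vessel_model`.
#' @export
vessel_model <- function(center_depth_mm = 22, diameter_mm = 5,
                         inclination_deg = 0, profile_bluntness = 4) {
  if (diameter_mm <= 0) stop_config("`diameter_mm` must be positive")
  if (profile_bluntness <= 0) stop_config("`profile_bluntness` must be positive")
  structure(
    list(center_depth_mm = center_depth_mm, diameter_mm = diameter_mm,
         inclination_deg = inclination_deg, profile_bluntness = profile_bluntness),
    class = "vessel_model")
}

#' Gate centre depths
#'
#' The gate centres are equally spaced with the first at the minimum depth and
#' the last at the maximum depth.
#'
#' @param geometry A [probe_geometry()].
#' @return Numeric vector of gate centre depths in mm, length `n_gates`.
#' @examples
#' gate_layout(probe_geometry(n_gates = 2)) # c(8, 45)
#' @export
gate_layout <- function(geometry) {
  stopifnot(inherits(geometry, "probe_geometry"))
  seq(geometry$gate_depth_min_mm, geometry$gate_depth_max_mm,
      length.out = geometry$n_gates)
}

#' Signed beam-to-flow angles for the two transducers
#'
#' With the flow axis inclined by `alpha` degrees relative to the casing
#' bisector's normal plane and the two beams at `-theta0` and `+theta0` from
#' the bisector, the signed angle between the flow vector and each beam axis is
#' `phi_1 = alpha - theta0` and `phi_2 = alpha + theta0`. The projected
#' (axial) velocity seen by transducer k is `v * cos(phi_k)`.
#'
#' @param alpha_deg Flow inclination in degrees (scalar or vector).
#' @param theta0_deg Fixed half-angle of the probe, degrees. Default 30.
#' @return A tibble with columns `transducer` (1, 2) and `phi_deg`, one row
#'   pair per input angle.
#' @examples
#' beam_flow_angle(0)   # -30 and +30
#' beam_flow_angle(10)  # -20 and +40
#' @export
beam_flow_angle <- function(alpha_deg, theta0_deg = 30) {
  if (any(abs(alpha_deg) >= 90 - theta0_deg))
    stop_config(sprintf(
      "inclination must satisfy |alpha| < %g degrees for this probe",
      90 - theta0_deg))
  phi <- as.vector(rbind(alpha_deg - theta0_deg, alpha_deg + theta0_deg))
  alpha_rep <- rep(alpha_deg, each = 2L)
  trans <- rep(c(1L, 2L), length(alpha_deg))
  tibble(alpha_deg = alpha_rep, transducer = trans, phi_deg = phi)
}

# Doppler shift (Hz) of velocity v (cm/s) seen along beam angle phi (deg)
doppler_shift_hz <- function(v_cm_s, f0, c_sound, phi_deg = 0) {
  2 * f0 * (v_cm_s / 100) * cos(deg2rad(phi_deg)) / c_sound
}

# inverse: velocity (cm/s) for Doppler shift f_d with assumed beam angle
doppler_velocity_cm_s <- function(f_hz, f0, c_sound, phi_deg = 0) {
  f_hz * c_sound / (2 * f0 * cos(deg2rad(phi_deg))) * 100
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf(
    "<probe_geometry> f0 %.1f MHz, +/-%g deg, %d gates %g-%g mm, PRF %g Hz\n",
    x$f0 / 1e6, x$half_angle_deg, x$n_gates,
    x$gate_depth_min_mm, x$gate_depth_max_mm, x$prf))
  invisible(x)
}

#' @export
print.vessel_model <- function(x, ...) {
  cat(sprintf(
    "<vessel_model> centre %g mm, diameter %g mm, inclination %g deg, bluntness %g\n",
    x$center_depth_mm, x$diameter_mm, x$inclination_deg, x$profile_bluntness))
  invisible(x)
}
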