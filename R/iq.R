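#' Synthesize dual-transducer multigate IQ from ground-truth traces
#'
#' The acquisition forward model of the virtual device. For each transducer
#' (beams at `-theta0` and `+theta0` to the casing bisector) and each depth
#' gate intersecting the vessel lumen, the complex baseband (IQ) slow-time
#' signal is a sum of at least `n_scatterers` moving-scatterer phasors. Each
#' scatterer sits at a fixed radius `r` in the lumen cross-section sampled by
#' the gate and moves with the blunt profile
#' `v_s(t) = v_centre(t) * (1 - (r/R)^bluntness)`, so its instantaneous
#' Doppler frequency is `f_d(t) = 2 f0 v_s(t) cos(phi_k) / c` and its phase is
#' the running integral of `2*pi*f_d`. Complex white noise is added at
#' `-snr_db` relative to the unit flow-signal power, and near-DC clutter
#' (stationary tissue + slow wall motion, modelled as a strong tone with a
#' random-walk phase) at `+clutter_db`. Gates outside the lumen contain only
#' clutter and noise.
#'
#' @param traces A `scenario_traces` object; `velocity_cm_s` is the signed
#'   centreline velocity.
#' @param geometry A [probe_geometry()].
#' @param vessel A [vessel_model()].
#' @param snr_db Flow-signal-to-noise ratio, dB. Default 20.
#' @param clutter_db Clutter-to-flow-signal ratio, dB. Default 40.
#' @param n_scatterers Scatterers per gate. Default 50; smaller values are
#'   allowed for controlled single-tone experiments but do not produce
#'   physical spectral broadening.
#' @param scatterer_placement `"random"` (default) draws scatterer positions
#'   uniformly over the lumen chord sampled by each gate; `"centerline"` puts
#'   all scatterers on the vessel axis (profile factor 1), giving a pure tone
#'   at the centreline Doppler frequency.
#' @param seed Optional integer seed.
#' @param alias One of `"warn"` or `"refuse"`: behaviour when the peak
#'   projected Doppler frequency exceeds the Nyquist limit `prf/2`.
#' @return An object of class `dual_iq_record`: `$iq` is a list of two
#'   complex matrices (slow-time samples x gates), plus `$prf`,
#'   `$gate_depths_mm`, `$t0`, `$geometry`, `$vessel`, `$snr_db`,
#'   `$clutter_db`, `$seed`.
#' @export
synthesize_iq <- function(traces, geometry = probe_geometry(),
                          vessel = vessel_model(), snr_db = 20,
                          clutter_db = 40, n_scatterers = 50,
                          scatterer_placement = c("random", "centerline"),
                          seed = NULL, alias = c("warn", "refuse")) {
  scatterer_placement <- match.arg(scatterer_placement)
  stopifnot(inherits(traces, "scenario_traces"),
            inherits(geometry, "probe_geometry"),
            inherits(vessel, "vessel_model"))
  alias <- match.arg(alias)
  dur <- max(traces$trace$time_s)
  if (dur < 1) stop_data("trace must be at least 1 s long")
  n_scatterers <- as.integer(n_scatterers)
  if (n_scatterers < 1) stop_config("`n_scatterers` must be >= 1")
  phis <- beam_flow_angle(vessel$inclination_deg,
                          geometry$half_angle_deg)$phi_deg
  vmax <- max(abs(traces$trace$velocity_cm_s))
  fmax <- max(abs(doppler_shift_hz(vmax, geometry$f0, geometry$c_sound, phis)))
  if (fmax >= geometry$prf / 2) {
    msg <- sprintf(
      "peak velocity %.1f cm/s gives Doppler shift %.0f Hz >= Nyquist %.0f Hz",
      vmax, fmax, geometry$prf / 2)
    if (alias == "refuse") stop_data(msg) else warn(msg)
  }
  prf <- geometry$prf
  n <- floor(dur * prf)
  t_prf <- seq_len(n) / prf - 1 / prf
  # centreline velocity on the PRF grid (m/s)
  v_prf <- approx(traces$trace$time_s, traces$trace$velocity_cm_s / 100,
                  xout = t_prf, rule = 2)$y
  depths <- gate_layout(geometry)
  R <- vessel$diameter_mm / 2
  dz <- depths - vessel$center_depth_mm
  in_lumen <- abs(dz) < R
  noise_amp <- 10^(-snr_db / 20) / sqrt(2)
  clutter_amp <- 10^(clutter_db / 20)

  with_seed_opt(seed, {
    iq <- lapply(1:2, function(k) {
      K <- 2 * geometry$f0 * cos(deg2rad(phis[k])) / geometry$c_sound # Hz per m/s
      cumphase <- 2 * pi * K * cumsum(v_prf) / prf
      m <- matrix(complex(real = rnorm(n * geometry$n_gates, 0, noise_amp),
                          imaginary = rnorm(n * geometry$n_gates, 0, noise_amp)),
                  nrow = n)
      for (g in seq_len(geometry$n_gates)) {
        # clutter: strong near-DC tone whose phase drifts as a random walk
        drift <- cumsum(rnorm(n, 0, 2 * pi * 2 / prf)) # ~2 Hz RMS wall motion
        m[, g] <- m[, g] + clutter_amp * exp(1i * (runif(1, 0, 2 * pi) + drift))
        if (in_lumen[g]) {
          chord <- sqrt(R^2 - dz[g]^2)
          x <- if (scatterer_placement == "centerline") rep(0, n_scatterers)
               else runif(n_scatterers, -chord, chord)
          r <- if (scatterer_placement == "centerline") rep(0, n_scatterers)
               else sqrt(dz[g]^2 + x^2)
          fac <- 1 - (r / R)^vessel$profile_bluntness
          ph0 <- runif(n_scatterers, 0, 2 * pi)
          amp <- rep(1 / sqrt(n_scatterers), n_scatterers)
          m[, g] <- m[, g] + phasor_sum(cumphase, fac, ph0, amp)
        }
      }
      m
    })
    structure(
      list(iq = iq, prf = prf, gate_depths_mm = depths, t0 = 0,
           geometry = geometry, vessel = vessel, snr_db = snr_db,
           clutter_db = clutter_db, n_scatterers = n_scatterers, seed = seed),
      class = "dual_iq_record")
  })
}

#' @export
print.dual_iq_record <- function(x, ...) {
  cat(sprintf(
    "<dual_iq_record> 2 transducers x %d gates x %d samples at PRF %g Hz (%.1f s)\n",
    ncol(x$iq[[1]]), nrow(x$iq[[1]]), x$prf, nrow(x$iq[[1]]) / x$prf))
  invisible(x)
}
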