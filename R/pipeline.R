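#' Run the full measurement chain on a dual IQ record
#'
#' Wall-filters both transducers, computes colour M-mode and selects the gate
#' with the strongest pulsatile flow per transducer, computes the spectrogram
#' and maximum-velocity envelope at the selected gates, detects beats on the
#' transducer-1 envelope, computes per-beat indices for both transducers on
#' the shared beat boundaries, estimates the inclination angle per beat from
#' the two TAVs, and classifies the flow state. Velocities in `psv`, `edv`,
#' `tav`, `tav2` are uncorrected (axial, transducer 1 unless suffixed);
#' `alpha_deg`, `speed_cm_s`, `psv_corr` and `edv_corr` are angle-corrected.
#'
#' @param iq A `dual_iq_record`.
#' @param wall_cutoff_hz Wall-filter cutoff, Hz. Default 100.
#' @param window_s,overlap_frac Spectrogram taper and overlap. Defaults
#'   0.01 s / 0.75.
#' @param percentile,noise_margin_db Envelope-tracer settings (see
#'   [trace_envelope()]).
#' @param min_interval_s,prominence Beat-detector settings (see
#'   [detect_beats()]).
#' @param frame_s M-mode frame length, s. Default 0.02.
#' @param ecg_events Optional ECG event times for the PEA classifier.
#' @param keep_spectrograms Keep the (large) spectrogram objects? Default
#'   FALSE.
#' @return Object of class `doppler_result`: `$selected` (gate per
#'   transducer), `$envelopes` (list of two `doppler_envelope`), `$metrics`
#'   (per-beat tibble), `$flow_state`, optionally `$spectrograms`.
#' @export
process_dual_iq <- function(iq, wall_cutoff_hz = 100, window_s = 0.01,
                            overlap_frac = 0.75, percentile = 0.95,
                            noise_margin_db = 8, min_interval_s = 0.25,
                            prominence = 10, frame_s = 0.02,
                            ecg_events = NULL, keep_spectrograms = FALSE) {
  stopifnot(inherits(iq, "dual_iq_record"))
  geom <- iq$geometry
  iq_f <- wall_filter(iq, cutoff_hz = wall_cutoff_hz)
  mm <- compute_color_mmode(iq_f, frame_s = frame_s)
  sel <- select_gate(mm)
  if (all(is.na(sel$gate))) {
    env0 <- tibble(t = mm$t[mm$transducer == 1 & mm$gate == 0],
                   v_max = 0, quality = "low")
    attr(env0, "frame_rate") <- 1 / frame_s
    class(env0) <- c("doppler_envelope", class(env0))
    metrics <- tibble(beat_idx = integer(), t_start = numeric(),
                      t_end = numeric(), psv = numeric(), edv = numeric(),
                      tav = numeric(), ri = numeric(), pi = numeric(),
                      hr = numeric())
    fs <- classify_flow_state(metrics, env0, ecg_events)
    return(structure(list(selected = sel, envelopes = NULL, metrics = metrics,
                          flow_state = fs, spectrograms = NULL),
                     class = "doppler_result"))
  }
  # fall back to the other transducer's gate if one side saw nothing
  gates <- ifelse(is.na(sel$gate), rev(sel$gate), sel$gate)
  specs <- lapply(1:2, function(k) {
    compute_spectrogram(iq_f$iq[[k]][, gates[k] + 1L], prf = geom$prf,
                        f0 = geom$f0, c_sound = geom$c_sound,
                        window_s = window_s, overlap_frac = overlap_frac)
  })
  envs <- lapply(specs, trace_envelope, percentile = percentile,
                 noise_margin_db = noise_margin_db)
  beats <- detect_beats(envs[[1]], min_interval_s = min_interval_s,
                        prominence = prominence)
  if (nrow(beats) > 0) {
    m1 <- compute_beat_metrics(envs[[1]], beats)
    m2 <- compute_beat_metrics(envs[[2]], beats)
    ang <- estimate_angle(m1$tav, m2$tav, geom$half_angle_deg)
    phi1 <- deg2rad(ang$alpha_deg - geom$half_angle_deg)
    phi2 <- deg2rad(ang$alpha_deg + geom$half_angle_deg)
    metrics <- m1 |>
      mutate(
        tav2 = m2$tav,
        alpha_deg = ang$alpha_deg,
        speed_cm_s = ang$speed,
        psv_corr = (m1$psv / cos(phi1) + m2$psv / cos(phi2)) / 2,
        edv_corr = (m1$edv / cos(phi1) + m2$edv / cos(phi2)) / 2)
  } else {
    metrics <- tibble(beat_idx = integer(), t_start = numeric(),
                      t_end = numeric(), psv = numeric(), edv = numeric(),
                      tav = numeric(), ri = numeric(), pi = numeric(),
                      hr = numeric(), tav2 = numeric(), alpha_deg = numeric(),
                      speed_cm_s = numeric(), psv_corr = numeric(),
                      edv_corr = numeric())
  }
  fs <- classify_flow_state(metrics, envs[[1]], ecg_events)
  structure(
    list(selected = sel, envelopes = envs, metrics = metrics,
         flow_state = fs,
         spectrograms = if (keep_spectrograms) specs else NULL),
    class = "doppler_result")
}

#' @export
print.doppler_result <- function(x, ...) {
  cat(sprintf("<doppler_result> gate t1=%s t2=%s, %d beats, states: %s\n",
              x$selected$gate[1], x$selected$gate[2], nrow(x$metrics),
              paste(unique(x$flow_state$state), collapse = "/")))
  invisible(x)
}

#' @method tidy doppler_result
#' @export
tidy.doppler_result <- function(x, ...) x$metrics
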