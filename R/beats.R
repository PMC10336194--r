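#' Detect heartbeats on a maximum-velocity envelope
#'
#' Systolic peaks are found by prominence-based peak detection with a
#' refractory minimum spacing; each beat's onset is the envelope minimum
#' between consecutive systolic peaks (the diastolic trough preceding the
#' upstroke). Beats are the inter-onset intervals. The device segments beats
#' from its own envelope — no ECG is needed.
#'
#' @param env A `doppler_envelope` (tibble with `t`, `v_max`).
#' @param min_interval_s Refractory interval between systolic peaks, s.
#'   Default 0.25 (maximum 240 bpm).
#' @param prominence Minimum peak prominence, cm/s. Default 10.
#' @param min_height Minimum absolute envelope value at a systolic peak,
#'   cm/s; defaults to `prominence`. Guards against low-lying wiggles next
#'   to deep reverse lobes, which can carry large prominence at near-zero
#'   velocity.
#' @return A tibble with one row per complete beat: `beat_idx`, `t_start`,
#'   `t_end`, `i_start`, `i_end` (frame indices). Empty (zero rows) when no
#'   pulsatile flow is present.
#' @export
detect_beats <- function(env, min_interval_s = 0.25, prominence = 10,
                         min_height = prominence) {
  stopifnot(is.data.frame(env), all(c("t", "v_max") %in% names(env)))
  if (max(env$t) - min(env$t) < 2) stop_data("envelope must cover at least 2 s")
  v <- env$v_max
  peaks <- find_peaks(v, min_dist = ceiling(min_interval_s /
                                              median(diff(env$t))),
                      min_prominence = prominence, min_height = min_height)
  if (length(peaks) < 2)
    return(tibble(beat_idx = integer(), t_start = numeric(),
                  t_end = numeric(), i_start = integer(), i_end = integer()))
  # onset of beat k: trough between peaks k-1 and k, refined to the systolic
  # upstroke (last point below trough + 15% of the rise) — the trough region
  # is flat in diastole, so the raw argmin jitters while the upstroke does not
  marks <- vapply(seq_len(length(peaks) - 1), function(k) {
    seg <- peaks[k]:peaks[k + 1]
    tr_i <- seg[which.min(v[seg])]
    thr <- v[tr_i] + 0.15 * (v[peaks[k + 1]] - v[tr_i])
    up <- tr_i:peaks[k + 1]
    below <- up[v[up] <= thr]
    c(onset = if (length(below)) max(below) else tr_i, trough = tr_i)
  }, integer(2))
  onsets <- marks["onset", ]
  troughs <- marks["trough", ]
  n_beats <- length(onsets) - 1
  if (n_beats < 1)
    return(tibble(beat_idx = integer(), t_start = numeric(),
                  t_end = numeric(), i_start = integer(), i_end = integer(),
                  i_trough_end = integer()))
  tibble(
    beat_idx = seq_len(n_beats),
    t_start = env$t[onsets[-length(onsets)]],
    t_end = env$t[onsets[-1]],
    i_start = onsets[-length(onsets)],
    i_end = onsets[-1],
    i_trough_end = troughs[-1])
}

# local maxima with prominence and refractory spacing (neither pracma nor
# signal expose prominence, so computed directly: the drop to the highest
# saddle separating the peak from any higher point on either side)
find_peaks <- function(v, min_dist = 1, min_prominence = 0, min_height = 0) {
  n <- length(v)
  if (n < 3) return(integer())
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  cand <- cand[v[cand] >= min_height]
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    h <- v[i]
    left <- v[seq_len(i - 1)]
    right <- v[(i + 1):n]
    hi_l <- which(left > h)
    hi_r <- which(right > h)
    base_l <- if (length(hi_l)) min(v[(max(hi_l) + 1):(i - 1)]) else min(left)
    base_r <- if (length(hi_r)) min(v[i + seq_len(min(hi_r) - 1)]) else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer())
  # enforce refractory spacing, keeping the taller of two close peaks
  ord <- keep[order(-v[keep])]
  sel <- integer()
  for (i in ord) if (!length(sel) || all(abs(sel - i) >= min_dist)) sel <- c(sel, i)
  sort(sel)
}

#' Per-beat hemodynamic indices
#'
#' For each detected beat: PSV (peak systolic velocity) is the envelope
#' maximum, EDV (end-diastolic velocity, signed) the envelope value at the
#' beat end, TAV the time average of the envelope over the beat,
#' `RI = (PSV - EDV)/PSV`, `PI = (PSV - EDV)/TAV` (`NaN` sentinel when
#' TAV = 0), and `HR = 60/period`. All velocities are in the envelope's own
#' (uncorrected axial) scale; RI, PI and HR are ratios or timings and are
#' unaffected by the insonation angle.
#'
#' EDV is read as the median envelope over a late-diastolic window just
#' before the beat-ending upstroke (4-12% of the period before the onset):
#' a median over ~20 frames is robust to the noise extremes that an argmin
#' at the trough would chase. Each beat also carries a `quality` score, the
#' fraction of its frames with above-noise signal; beats whose diastolic
#' flow falls below the wall-filter cutoff are low-quality by construction
#' and should be treated accordingly.
#'
#' @param env A `doppler_envelope`.
#' @param beats Output of [detect_beats()].
#' @return A `beat_metrics` tibble: `beat_idx`, `t_start`, `t_end`, `psv`,
#'   `edv`, `tav`, `ri`, `pi`, `hr`, `quality`.
#' @examples
#' env <- tibble::tibble(t = seq(0, 0.8, by = 0.001),
#'                       v_max = rep(c(100, 20), c(201, 600)))
#' # rectangular beat: PSV 100, EDV 20, TAV 40, RI 0.8, PI 2, HR 75
#' @export
compute_beat_metrics <- function(env, beats) {
  if (nrow(beats) < 1) stop_data("no beats to compute metrics for")
  out <- lapply(seq_len(nrow(beats)), function(k) {
    idx <- beats$i_start[k]:(beats$i_end[k] - 1L)
    v <- env$v_max[idx]
    psv <- max(v)
    # end-diastole: late-diastolic window before the beat-ending upstroke
    period_frames <- beats$i_end[k] - beats$i_start[k]
    k1 <- max(3L, round(0.12 * period_frames))
    k2 <- max(1L, round(0.04 * period_frames))
    tail_idx <- max(beats$i_start[k], beats$i_end[k] - k1):
      (beats$i_end[k] - k2)
    edv <- median(env$v_max[tail_idx])
    tav <- mean(v)
    qual <- if ("quality" %in% names(env)) mean(env$quality[idx] == "ok")
            else 1
    tibble(
      beat_idx = beats$beat_idx[k],
      t_start = beats$t_start[k], t_end = beats$t_end[k],
      psv = psv, edv = edv, tav = tav,
      ri = (psv - edv) / psv,
      pi = if (tav == 0) NaN else (psv - edv) / tav,
      hr = 60 / (beats$t_end[k] - beats$t_start[k]),
      quality = qual)
  })
  out <- bind_rows(out)
  class(out) <- c("beat_metrics", class(out))
  out
}

#' Dual-transducer angle estimation and velocity correction
#'
#' The two transducers see the projected velocities
#' `tav1 = v cos(alpha - theta0)` and `tav2 = v cos(alpha + theta0)`.
#' Expanding the cosines and dividing gives the unique two-unknown inversion
#' `alpha = atan( (tav1 - tav2) / ((tav1 + tav2) tan(theta0)) )` and
#' `v = (tav1 + tav2) / (2 cos(theta0) cos(alpha))`, which reproduces the two
#' inputs exactly when forward-projected.
#'
#' @param tav1,tav2 Per-transducer time-averaged velocities, cm/s
#'   (vectorized).
#' @param theta0_deg Fixed probe half-angle, degrees. Default 30.
#' @return A tibble with columns `alpha_deg` (estimated inclination) and
#'   `speed` (angle-corrected velocity, cm/s).
#' @examples
#' estimate_angle(40, 20) # alpha 30 deg, speed 40 cm/s
#' @export
estimate_angle <- function(tav1, tav2, theta0_deg = 30) {
  if (any(abs(tav1 + tav2) < 1e-12))
    stop_data("tav1 + tav2 = 0: inclination is indeterminate")
  th <- deg2rad(theta0_deg)
  alpha <- atan((tav1 - tav2) / ((tav1 + tav2) * tan(th)))
  speed <- (tav1 + tav2) / (2 * cos(th) * cos(alpha))
  tibble(alpha_deg = rad2deg(alpha), speed = speed)
}

#' Classify flow state per 2-second window
#'
#' Operationalizes the pulse check: each window is `pulsatile` when beats are
#' detected in it and the windowed PSV reaches `pulsatile_threshold`;
#' otherwise `low_flow_pea` when organized ECG events are present but flow is
#' absent or below `pea_threshold`; otherwise `no_flow`. Confidence is a
#' crude margin score in [0, 1].
#'
#' @param metrics A `beat_metrics` tibble (may have zero rows).
#' @param env The `doppler_envelope` the metrics came from.
#' @param ecg_events Optional numeric vector of ECG beat-event times, s.
#'   Without it the `low_flow_pea` state cannot be assigned.
#' @param window_s Window length, s. Default 2.
#' @param pulsatile_threshold Minimum windowed PSV for pulsatile flow, cm/s.
#'   Default 20. (Operational default, not a literature value.)
#' @param pea_threshold TAV below which organized ECG without pulsatile flow
#'   is called PEA, cm/s. Default 12.
#' @return A `flow_state_series` tibble: `t_start`, `t_end`, `state`
#'   (`pulsatile`/`no_flow`/`low_flow_pea`), `confidence`.
#' @export
classify_flow_state <- function(metrics, env, ecg_events = NULL,
                                window_s = 2, pulsatile_threshold = 20,
                                pea_threshold = 12) {
  t_max <- max(env$t)
  if (t_max < window_s) stop_data("record must cover at least one window")
  edges <- seq(0, t_max, by = window_s)
  if (tail(edges, 1) < t_max) edges <- c(edges, t_max)
  out <- lapply(seq_len(length(edges) - 1), function(w) {
    t0 <- edges[w]; t1 <- edges[w + 1]
    in_win <- env$t >= t0 & env$t < t1
    v <- env$v_max[in_win]
    beats_in <- nrow(metrics) > 0 &&
      any(metrics$t_start < t1 & metrics$t_end > t0)
    psv_win <- if (length(v)) max(abs(v)) else 0
    tav_win <- if (length(v)) mean(abs(v)) else 0
    ecg_in <- !is.null(ecg_events) && any(ecg_events >= t0 & ecg_events < t1)
    if (beats_in && psv_win >= pulsatile_threshold) {
      state <- "pulsatile"
      conf <- min(1, psv_win / (2 * pulsatile_threshold))
    } else if (ecg_in) {
      state <- "low_flow_pea"
      conf <- min(1, max(0, 1 - tav_win / pea_threshold))
    } else {
      state <- "no_flow"
      conf <- min(1, max(0, 1 - psv_win / pulsatile_threshold))
    }
    tibble(t_start = t0, t_end = t1, state = state, confidence = conf)
  })
  out <- bind_rows(out)
  class(out) <- c("flow_state_series", class(out))
  out
}
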