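#' Doppler spectrogram of one gate
#'
#' Short-time Fourier magnitude-squared of the slow-time IQ signal with a
#' Hann taper, frequency axis mapped to velocity through the Doppler
#' equation `v = c f / (2 f0 cos(phi_assumed))`. By default no angle is
#' assumed (`cos(phi) = 1`), i.e. the axis is the uncorrected axial velocity;
#' angle correction happens later, at the TAV stage.
#'
#' @param iq_gate Complex slow-time vector of the selected gate.
#' @param prf Pulse repetition frequency, Hz.
#' @param f0 Carrier frequency, Hz.
#' @param c_sound Speed of sound, m/s.
#' @param window_s Taper length, s. Default 0.01 (10 ms).
#' @param overlap_frac Fractional overlap of consecutive windows. Default
#'   0.75.
#' @param nfft FFT length (zero-padded). Default next power of two >= window.
#' @param phi_assumed_deg Beam-to-flow angle assumed for the velocity axis,
#'   degrees. Default 0 (uncorrected).
#' @return Object of class `doppler_spectrogram`: `$t` frame centres (s),
#'   `$velocity` signed velocity axis (cm/s, increasing), `$power` matrix
#'   (velocity bins x frames), plus acquisition metadata.
#' @export
compute_spectrogram <- function(iq_gate, prf, f0 = 4e6, c_sound = 1540,
                                window_s = 0.01, overlap_frac = 0.75,
                                nfft = NULL, phi_assumed_deg = 0) {
  nwin <- round(window_s * prf)
  if (nwin < 4) stop_config("window too short for this PRF")
  if (length(iq_gate) < 2 * nwin)
    stop_data("record must cover at least two analysis windows")
  hop <- max(1L, round(nwin * (1 - overlap_frac)))
  if (is.null(nfft)) nfft <- 2^ceiling(log2(nwin))
  starts <- seq(1L, length(iq_gate) - nwin + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nwin) / (nwin + 1))) # Hann
  # frames as columns; single batched FFT
  frames <- matrix(0+0i, nrow = nfft, ncol = length(starts))
  for (j in seq_along(starts)) {
    frames[seq_len(nwin), j] <- iq_gate[starts[j] + seq_len(nwin) - 1L] * w
  }
  spec <- stats::mvfft(frames)
  pow <- Mag2(spec) / sum(w^2)
  # fftshift so frequency runs -prf/2 .. +prf/2
  shift <- c((nfft / 2 + 1):nfft, 1:(nfft / 2))
  pow <- pow[shift, , drop = FALSE]
  freq <- ((0:(nfft - 1)) - nfft / 2) * prf / nfft
  vel <- doppler_velocity_cm_s(freq, f0, c_sound, phi_assumed_deg)
  structure(
    list(t = (starts - 1 + nwin / 2) / prf, velocity = vel, power = pow,
         prf = prf, f0 = f0, c_sound = c_sound,
         frame_rate = prf / hop, bin_cm_s = diff(vel[1:2]),
         phi_assumed_deg = phi_assumed_deg),
    class = "doppler_spectrogram")
}

Mag2 <- function(z) Re(z)^2 + Im(z)^2

#' @export
print.doppler_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<doppler_spectrogram> %d frames x %d bins, %.1f cm/s/bin, frame rate %.0f Hz\n",
    ncol(x$power), nrow(x$power), x$bin_cm_s, x$frame_rate))
  invisible(x)
}

#' @method tidy doppler_spectrogram
#' @export
tidy.doppler_spectrogram <- function(x, ...) {
  tibble(
    t = rep(x$t, each = length(x$velocity)),
    velocity = rep(x$velocity, length(x$t)),
    power = as.vector(x$power))
}

#' Trace the maximum-velocity envelope from a spectrogram
#'
#' Per frame, the noise floor is estimated as the median bin power times a
#' margin; for each flow direction the envelope candidate is the smallest
#' |velocity| whose cumulative above-noise in-direction power reaches
#' `percentile` of that direction's total. The composite signed envelope
#' takes the direction holding more above-noise power, then is median
#' smoothed over `smooth_frames` frames. Frames with no above-noise power are
#' flagged low-quality and carry an envelope of 0 — the envelope is defined
#' on every frame, never gapped.
#'
#' @param spec A `doppler_spectrogram`.
#' @param percentile Cumulative-power fraction defining the envelope.
#'   Default 0.95.
#' @param noise_margin_db Margin above the per-frame median power that counts
#'   as signal, dB. Default 8.
#' @param smooth_frames Running-median width (odd). Default 5.
#' @return Object of class `doppler_envelope`: a tibble with columns `t`,
#'   `v_max` (signed, cm/s) and `quality` (`"ok"`/`"low"`), with the frame
#'   rate and velocity-bin width as attributes.
#' @export
trace_envelope <- function(spec, percentile = 0.95, noise_margin_db = 8,
                           smooth_frames = 5) {
  stopifnot(inherits(spec, "doppler_spectrogram"))
  if (ncol(spec$power) < 1) stop_data("empty spectrogram")
  pow <- spec$power
  vel <- spec$velocity
  floor_per_frame <- apply(pow, 2, median)
  thr <- floor_per_frame * 10^(noise_margin_db / 10)
  above <- sweep(pow, 2, thr, `-`)
  above[above < 0] <- 0
  pos <- which(vel > 0)
  neg <- which(vel < 0)
  pos <- pos[order(vel[pos])] # increasing |v|
  neg <- neg[order(-vel[neg])]
  env_dir <- function(idx) {
    a <- above[idx, , drop = FALSE]
    tot <- colSums(a)
    cum <- apply(a, 2, cumsum)
    target <- percentile * tot
    # first bin index (from slow outward) reaching the target
    k <- colSums(sweep(cum, 2, target, `<`)) + 1L
    k <- pmin(k, length(idx))
    list(v = abs(vel[idx])[k], power = tot)
  }
  ep <- env_dir(pos)
  en <- env_dir(neg)
  use_pos <- ep$power >= en$power
  v <- ifelse(use_pos, ep$v, -en$v)
  # a frame carries flow only if its above-noise power clearly exceeds what
  # noise alone leaks past the margin (~1% of bins for an 8 dB margin)
  quality <- ifelse(
    ep$power + en$power <= 0.1 * nrow(pow) * floor_per_frame, "low", "ok")
  v[quality == "low"] <- 0
  if (smooth_frames > 1 && length(v) > smooth_frames)
    v <- stats::runmed(v, k = smooth_frames, endrule = "median")
  out <- tibble(t = spec$t, v_max = as.numeric(v), quality = quality)
  attr(out, "frame_rate") <- spec$frame_rate
  attr(out, "bin_cm_s") <- spec$bin_cm_s
  class(out) <- c("doppler_envelope", class(out))
  out
}

#' Build an envelope directly from ground-truth traces
#'
#' Resamples a scenario's centreline velocity onto an envelope frame grid, so
#' beat detection and flow-state classification can run on simulator output
#' without the acquisition model — useful for fast property checks and as a
#' processing oracle.
#'
#' @param traces A `scenario_traces` object.
#' @param frame_rate Envelope frame rate, Hz. Default 50.
#' @return A `doppler_envelope` tibble (`t`, `v_max`, `quality`).
#' @export
as_envelope <- function(traces, frame_rate = 50) {
  stopifnot(inherits(traces, "scenario_traces"))
  t_out <- seq(0, max(traces$trace$time_s), by = 1 / frame_rate)
  v <- approx(traces$trace$time_s, traces$trace$velocity_cm_s, xout = t_out,
              rule = 2)$y
  out <- tibble(t = t_out, v_max = v, quality = "ok")
  attr(out, "frame_rate") <- frame_rate
  attr(out, "bin_cm_s") <- NA_real_
  class(out) <- c("doppler_envelope", class(out))
  out
}
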