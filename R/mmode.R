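#' Colour M-mode: mean velocity and power per gate and frame
#'
#' For every gate and analysis frame, the mean velocity is estimated from the
#' phase of the lag-1 slow-time autocorrelation (the classic autocorrelation
#' / Kasai estimator): `v = c * prf * arg(R(1)) / (4 pi f0)`. Power is the
#' mean squared magnitude. Velocities are uncorrected (axial). Frames with
#' zero signal get velocity 0 by convention.
#'
#' @param iq A `dual_iq_record` (both transducers are processed) or a complex
#'   matrix (samples x gates) with `prf`, `f0`, `c_sound` supplied.
#' @param frame_s Frame length, s. Default 0.02.
#' @param prf,f0,c_sound Acquisition parameters for bare-matrix input.
#' @return Object of class `color_mmode`: tibble with columns `transducer`,
#'   `gate`, `depth_mm`, `t`, `mean_velocity` (cm/s), `power`; frame rate in
#'   attributes.
#' @export
compute_color_mmode <- function(iq, frame_s = 0.02, prf = NULL, f0 = 4e6,
                                c_sound = 1540) {
  if (inherits(iq, "dual_iq_record")) {
    res <- lapply(1:2, function(k) {
      out <- mmode_matrix(iq$iq[[k]], frame_s, iq$prf, iq$geometry$f0,
                          iq$geometry$c_sound)
      out$transducer <- k
      out$depth_mm <- iq$gate_depths_mm[out$gate + 1L]
      out
    })
    out <- bind_rows(res)
    attr(out, "frame_s") <- frame_s
    class(out) <- c("color_mmode", class(out))
    return(out)
  }
  if (is.null(prf)) stop_config("`prf` is required for bare signals")
  out <- mmode_matrix(as.matrix(iq), frame_s, prf, f0, c_sound)
  out$transducer <- 1L
  out$depth_mm <- NA_real_
  attr(out, "frame_s") <- frame_s
  class(out) <- c("color_mmode", class(out))
  out
}

mmode_matrix <- function(m, frame_s, prf, f0, c_sound) {
  nwin <- round(frame_s * prf)
  if (nwin < 2) stop_config("frame too short for this PRF")
  nframes <- floor(nrow(m) / nwin)
  if (nframes < 1) stop_data("record shorter than one frame")
  n_use <- nframes * nwin
  frame_id <- rep(seq_len(nframes), each = nwin)
  out <- vector("list", ncol(m))
  for (g in seq_len(ncol(m))) {
    x <- m[seq_len(n_use), g]
    lag <- Conj(x[-n_use]) * x[-1]
    lag[frame_id[-n_use] != frame_id[-1]] <- 0+0i # no straddling products
    r1 <- rowsum(Re(lag), frame_id[-n_use]) + 1i * rowsum(Im(lag), frame_id[-n_use])
    pw <- rowsum(Mag2(x), frame_id) / nwin
    v <- c_sound * prf * Arg(r1) / (4 * pi * f0) * 100 # cm/s
    v[Mod(r1) == 0] <- 0
    out[[g]] <- tibble(
      gate = g - 1L, t = (seq_len(nframes) - 0.5) * frame_s,
      mean_velocity = as.numeric(v), power = as.numeric(pw))
  }
  bind_rows(out)
}

#' Select the gate with the strongest pulsatile flow
#'
#' Scores every gate by (variance of its mean-velocity trace within the
#' 0.5-4 Hz heart-rate band) x (mean power), and picks the maximum per
#' transducer; ties break toward the shallower gate. If no gate scores above
#' `min_score`, the record is considered flow-free and `NA` is returned for
#' that transducer (the no-flow sentinel).
#'
#' @param mmode A `color_mmode`.
#' @param band_hz Pulsatility band, Hz. Default `c(0.5, 4)`.
#' @param min_score Minimum pulsatile score (band velocity variance in
#'   (cm/s)^2 times normalized power). Default 1.
#' @return A tibble with one row per transducer: `transducer`, `gate`
#'   (0-based, `NA` if no flow), `depth_mm`, `score`.
#' @export
select_gate <- function(mmode, band_hz = c(0.5, 4), min_score = 1) {
  stopifnot(inherits(mmode, "color_mmode"))
  frame_s <- attr(mmode, "frame_s")
  fr <- 1 / frame_s
  scores <- mmode |>
    group_by(.data$transducer, .data$gate, .data$depth_mm) |>
    summarise(
      score = band_variance(.data$mean_velocity, fr, band_hz) * mean(.data$power),
      n = n(), .groups = "drop")
  if (any(scores$n < fr)) stop_data("need at least 1 s of frames")
  scores |>
    group_by(.data$transducer) |>
    arrange(dplyr::desc(.data$score), .data$gate, .by_group = TRUE) |>
    summarise(
      gate = ifelse(first(.data$score) >= min_score, first(.data$gate), NA_integer_),
      depth_mm = ifelse(first(.data$score) >= min_score, first(.data$depth_mm), NA_real_),
      score = first(.data$score), .groups = "drop")
}

# variance of the band-limited component of x sampled at rate fs
band_variance <- function(x, fs, band) {
  n <- length(x)
  if (n < 4) return(0)
  X <- stats::fft(x - mean(x))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # two-sided
  keep <- f >= band[1] & f <= band[2]
  sum(Mag2(X[keep])) / n^2
}
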