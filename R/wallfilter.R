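#' Wall (clutter) filter
#'
#' Zero-phase high-pass filtering along slow time to reject near-DC clutter
#' from stationary and slowly moving tissue. The filter applies the
#' magnitude-squared response of an `order`-th order Butterworth high-pass
#' (i.e. the response of a forward-backward pass) in the frequency domain:
#' `G(f) = 1 / (1 + (fc/|f|)^(2*order))`, with `G(0) = 0`. DC is removed
#' entirely, and tones above twice the cutoff are attenuated by less than
#' 0.1 dB.
#'
#' @param x A `dual_iq_record`, a complex matrix (samples x gates), or a
#'   complex vector for a single gate.
#' @param cutoff_hz High-pass cutoff, Hz. Default 100. Must be below
#'   `prf / 4`.
#' @param prf Pulse repetition frequency, Hz (taken from the record when `x`
#'   is a `dual_iq_record`).
#' @param order Butterworth order. Default 4.
#' @return Same shape as the input, filtered.
#' @export
wall_filter <- function(x, cutoff_hz = 100, prf = NULL, order = 4) {
  if (inherits(x, "dual_iq_record")) {
    x$iq <- lapply(x$iq, wall_filter, cutoff_hz = cutoff_hz, prf = x$prf,
                   order = order)
    x$wall_filtered <- TRUE
    return(x)
  }
  if (is.null(prf)) stop_config("`prf` is required for bare signals")
  if (cutoff_hz >= prf / 4)
    stop_config("`cutoff_hz` must be below prf/4")
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  f <- (seq_len(n) - 1) * prf / n
  f <- pmin(f, prf - f) # two-sided |frequency|
  gain <- ifelse(f == 0, 0, 1 / (1 + (cutoff_hz / f)^(2 * order)))
  out <- stats::mvfft(stats::mvfft(x) * gain, inverse = TRUE) / n
  if (vec) out[, 1] else out
}
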