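#' Parametric carotid beat template
#'
#' A single cardiac cycle of centreline blood velocity, built from a
#' raised-cosine systolic lobe, an optional raised-cosine reverse lobe in early
#' diastole (high-resistance triphasic flow), and a constant diastolic tail.
#' The tail value is the end-diastolic velocity of the beat.
#'
#' @param systolic_amplitude Peak systolic velocity, cm/s.
#' @param systolic_duration Duration of the systolic lobe, s.
#' @param diastolic_level Diastolic tail velocity (signed), cm/s; this is the
#'   end-diastolic velocity of the beat.
#' @param reverse_amplitude Magnitude (>= 0) of the early-diastolic reverse
#'   lobe, cm/s; when positive the waveform dips to `-reverse_amplitude`.
#' @param period Cycle length, s.
#' @param reverse_duration Duration of the reverse lobe, s; defaults to 20% of
#'   the period (capped by the available diastole).
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(systolic_amplitude, systolic_duration,
                          diastolic_level, reverse_amplitude = 0,
                          period, reverse_duration = NULL) {
  if (!is.finite(period) || period <= 0) stop_config("`period` must be positive")
  if (!is.finite(systolic_duration) || systolic_duration <= 0 ||
      systolic_duration >= period)
    stop_config("`systolic_duration` must satisfy 0 < duration < period")
  if (systolic_amplitude <= diastolic_level)
    stop_config("`systolic_amplitude` must exceed `diastolic_level`")
  if (reverse_amplitude < 0) stop_config("`reverse_amplitude` must be >= 0")
  if (is.null(reverse_duration))
    reverse_duration <- min(0.2 * period, period - systolic_duration)
  structure(
    list(systolic_amplitude = systolic_amplitude,
         systolic_duration = systolic_duration,
         diastolic_level = diastolic_level,
         reverse_amplitude = reverse_amplitude,
         period = period,
         reverse_duration = reverse_duration),
    class = "beat_template")
}

#' Evaluate a beat template on a time grid
#'
#' @param template A [beat_template()].
#' @param t_grid Times in s within one period (`0 <= t < period`).
#' @param shape `"cosine"` (default) for raised-cosine lobes or `"rect"` for a
#'   degenerate rectangular beat (flat-top systole at the systolic amplitude,
#'   diastole at the tail level) useful as a closed-form oracle.
#' @return Numeric velocity series in cm/s, same length as `t_grid`.
#' @examples
#' tpl <- beat_template(100, 0.2, 20, period = 0.8)
#' mean(gen_beat_waveform(tpl, seq(0, 0.8, length.out = 801)[-801], shape = "rect"))
#' @export
gen_beat_waveform <- function(template, t_grid, shape = c("cosine", "rect")) {
  stopifnot(inherits(template, "beat_template"))
  shape <- match.arg(shape)
  if (any(t_grid < 0 | t_grid >= template$period))
    stop_config("`t_grid` must lie within one period [0, period)")
  ts <- template$systolic_duration
  tr <- template$reverse_duration
  d <- template$diastolic_level
  A <- template$systolic_amplitude
  r <- template$reverse_amplitude
  v <- rep(d, length(t_grid))
  sys <- t_grid < ts
  if (shape == "rect") {
    v[sys] <- A
  } else {
    v[sys] <- d + (A - d) * 0.5 * (1 - cos(2 * pi * t_grid[sys] / ts))
    if (r > 0 && tr > 0) {
      rev <- t_grid >= ts & t_grid < ts + tr
      depth <- d + r # from tail level down to -r
      if (depth > 0) {
        u <- (t_grid[rev] - ts) / tr
        v[rev] <- d - depth * 0.5 * (1 - cos(2 * pi * u))
      }
    }
  }
  v
}

# closed-form time average of the cosine-shaped template over one period
beat_template_mean <- function(template) {
  p <- template$period
  d <- template$diastolic_level
  fs <- template$systolic_duration / p
  m <- d + fs * (template$systolic_amplitude - d) / 2
  if (template$reverse_amplitude > 0 && (d + template$reverse_amplitude) > 0) {
    fr <- template$reverse_duration / p
    m <- m - fr * (d + template$reverse_amplitude) / 2
  }
  m
}

# invert the closed-form mean for the systolic amplitude that yields a target
# time-averaged velocity, given tail level and reverse lobe
solve_systolic_amplitude <- function(tav, diastolic_level, reverse_amplitude,
                                     period, systolic_duration,
                                     reverse_duration) {
  fs <- systolic_duration / period
  m_rev <- 0
  if (reverse_amplitude > 0 && (diastolic_level + reverse_amplitude) > 0) {
    fr <- reverse_duration / period
    m_rev <- fr * (diastolic_level + reverse_amplitude) / 2
  }
  diastolic_level + 2 * (tav - diastolic_level + m_rev) / fs
}
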