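#' Scenario configuration
#'
#' Parameters of a single simulated hemodynamic scenario. Defaults are
#' calibrated so that a default VCO (vena cava occlusion) sequence reproduces
#' the study anchor means: baseline MAP 86 mmHg falling to 23, baseline SBP
#' 111 to a nadir of 33 (below the 60 mmHg termination rule), baseline TAV
#' ~37 cm/s falling to ~16, and end-diastolic velocity running from +10 cm/s
#' at baseline to -29 cm/s (high-resistance triphasic reverse flow) at the
#' nadir, with reverse flow appearing only once SBP < 80 mmHg.
#'
#' @param kind One of `"baseline"`, `"vco"`, `"vf"`, `"pea"`.
#' @param duration_s Scenario duration in s (for VCO: occlusion time from
#'   inflation to deflation). Defaults: vco 50, vf 60, pea 30, baseline 30.
#' @param lead_in_s Baseline hold before the scenario proper starts, s
#'   (baseline variables are read from this window). Default 10 for VCO,
#'   0 otherwise.
#' @param baseline_map,nadir_map Mean arterial pressure endpoints, mmHg.
#' @param baseline_sbp,nadir_sbp Systolic pressure endpoints, mmHg. A VCO
#'   config must have `nadir_sbp < 60`.
#' @param baseline_dbp,nadir_dbp Diastolic pressure endpoints, mmHg.
#' @param baseline_edv,nadir_edv End-diastolic centreline velocity endpoints,
#'   cm/s (signed; the nadir value is negative: reverse flow).
#' @param reverse_onset_sbp SBP below which the diastolic velocity ramps from
#'   its baseline value toward `nadir_edv`, mmHg. Default 80.
#' @param heart_rate Beats per minute. Default 100.
#' @param tav_map_intercept,tav_map_slope,tav_map_quad Coupling of beat
#'   time-averaged velocity (cm/s) to instantaneous MAP:
#'   `TAV = intercept + slope * MAP + quad * MAP^2`. Defaults 8.3, 0.333, 0,
#'   giving TAV 36.9 at MAP 86 and 16.0 at MAP 23.
#' @param vf_onset_s Time of fibrillation onset, s (VF scenarios).
#' @param vf_max_duration_s Maximum untreated VF before defibrillation, s
#'   (must be <= 60).
#' @param defib_delay_s Actual delay from VF onset to successful
#'   defibrillation, s; must not exceed `vf_max_duration_s`. Default 30.
#' @param vf_marker_s Duration of the broadband-noise onset marker, s
#'   (default 1.5, within the 1-2 s the fibrillating myocardium produces).
#' @param vf_marker_sd Velocity SD of the broadband marker, cm/s.
#' @param vf_pressure Non-pulsatile arterial pressure during arrest, mmHg.
#' @param vf_episode_interval_s Onset-to-onset spacing of consecutive VF
#'   episodes, s. Default 300 (5 minutes).
#' @param pea_sbp,pea_dbp Systolic/diastolic pressure during true PEA, mmHg.
#' @param pea_velocity Mean flow velocity during true PEA, cm/s. Default 10.
#' @param pea_modulation Fractional ECG-locked amplitude modulation of the
#'   PEA velocity (near-pulseless: <= 0.2). Default 0.15.
#' @param noise_sd Additive velocity noise SD, cm/s. Default 1.5.
#' @param map_noise_cv Multiplicative beat-level coefficient of variation of
#'   the pressure decline. Default 0.02.
#' @param systolic_frac,reverse_frac Systolic-lobe and reverse-lobe durations
#'   as fractions of the cardiac period. Defaults 0.55 and 0.2.
#' @param fs Trace sample rate, Hz. Default 100.
#' @param sync_interval_s Sync-pulse spacing, s. Default 6.
#' @param sync_jitter_sd Sync-pulse timing jitter SD, s. Default 0.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(kind = c("vco", "vf", "pea", "baseline"),
                            duration_s = NULL, lead_in_s = NULL,
                            baseline_map = 86, nadir_map = 23,
                            baseline_sbp = 111, nadir_sbp = 33,
                            baseline_dbp = 66, nadir_dbp = 18,
                            baseline_edv = 10, nadir_edv = -29,
                            reverse_onset_sbp = 80,
                            heart_rate = 100,
                            tav_map_intercept = 8.3, tav_map_slope = 0.333,
                            tav_map_quad = 0,
                            vf_onset_s = 15, vf_max_duration_s = 60,
                            defib_delay_s = 30,
                            vf_marker_s = 1.5, vf_marker_sd = 25,
                            vf_pressure = 15,
                            vf_episode_interval_s = 300,
                            pea_sbp = 20, pea_dbp = 12,
                            pea_velocity = 10, pea_modulation = 0.15,
                            noise_sd = 1.5, map_noise_cv = 0.02,
                            systolic_frac = 0.55, reverse_frac = 0.2,
                            fs = 100,
                            sync_interval_s = 6, sync_jitter_sd = 0) {
  kind <- match.arg(kind)
  if (is.null(duration_s))
    duration_s <- switch(kind, vco = 50, vf = 60, pea = 30, baseline = 30)
  if (is.null(lead_in_s)) lead_in_s <- if (kind == "vco") 10 else 0
  cfg <- structure(as.list(environment()), class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  with(cfg, {
    if (duration_s <= 0) stop_config("`duration_s` must be positive")
    if (heart_rate <= 0) stop_config("`heart_rate` must be positive")
    if (fs <= 0) stop_config("`fs` must be positive")
    if (any(c(baseline_map, nadir_map, baseline_sbp, nadir_sbp,
              baseline_dbp, nadir_dbp, pea_sbp, pea_dbp, vf_pressure) <= 0))
      stop_config("all pressures must be positive")
    if (kind == "vco") {
      if (nadir_map >= baseline_map || nadir_sbp >= baseline_sbp)
        stop_config("VCO nadir pressures must be below baseline")
      if (nadir_sbp >= 60)
        stop_config("VCO termination rule requires `nadir_sbp` < 60 mmHg")
    }
    if (kind == "vf") {
      if (vf_max_duration_s > 60)
        stop_config("`vf_max_duration_s` must not exceed 60 s")
      if (defib_delay_s > vf_max_duration_s)
        stop_config("`defib_delay_s` must not exceed `vf_max_duration_s`")
      if (vf_onset_s >= duration_s)
        stop_config("`vf_onset_s` must fall before the end of the record")
    }
    if (pea_modulation < 0 || pea_modulation > 0.2)
      stop_config("`pea_modulation` must lie in [0, 0.2] (near-pulseless flow)")
    if (noise_sd < 0 || map_noise_cv < 0)
      stop_config("noise parameters must be >= 0")
  })
  invisible(cfg)
}

# constructor for the traces container
new_scenario_traces <- function(trace, beats, ecg_events, sync_pulses,
                                segments, config, tav_offset = 0) {
  structure(
    list(trace = trace, beats = beats, ecg_events = ecg_events,
         sync_pulses = sync_pulses, segments = segments,
         config = config, tav_offset = tav_offset),
    class = "scenario_traces")
}

#' @export
print.scenario_traces <- function(x, ...) {
  dur <- if (nrow(x$trace)) max(x$trace$time_s) else max(x$beats$t_end)
  cat(sprintf("<scenario_traces> kind '%s', %.1f s at %g Hz, %d beats, %d sync pulses\n",
              x$config$kind, dur, x$config$fs,
              nrow(x$beats), length(x$sync_pulses)))
  invisible(x)
}

#' @method as_tibble scenario_traces
#' @export
as_tibble.scenario_traces <- function(x, ...) x$trace

# mark the trace samples nearest a set of event times with 1
event_indicator <- function(time_s, events) {
  ind <- integer(length(time_s))
  if (length(events)) {
    idx <- round(approx(time_s, seq_along(time_s), xout = events,
                        rule = 2)$y)
    ind[unique(idx)] <- 1L
  }
  ind
}

#' Sync-pulse channel
#'
#' Event times of the synchronization pulse generator: one pulse every
#' `interval_s` seconds (plus optional timing jitter), starting at t = 0.
#'
#' @param duration_s Record length, s.
#' @param interval_s Pulse spacing, s. Default 6.
#' @param jitter_sd Per-pulse Gaussian timing jitter SD, s. Default 0.
#' @param seed Optional integer seed for the jitter draws.
#' @return Sorted numeric vector of pulse times in s.
#' @examples
#' diff(gen_sync_channel(60)) # ten intervals of exactly 6 s
#' @export
gen_sync_channel <- function(duration_s, interval_s = 6, jitter_sd = 0,
                             seed = NULL) {
  if (interval_s <= 0) stop_config("`interval_s` must be positive")
  k <- seq(0, floor(duration_s / interval_s))
  with_seed_opt(seed, {
    t <- k * interval_s + if (jitter_sd > 0) rnorm(length(k), 0, jitter_sd) else 0
    sort(pmax(t, 0))
  })
}

# per-beat levels along the VCO decline; frac in [0,1] is ramp position
vco_beat_levels <- function(cfg, frac, noise_factor = 1) {
  map <- (cfg$baseline_map + frac * (cfg$nadir_map - cfg$baseline_map)) * noise_factor
  sbp <- (cfg$baseline_sbp + frac * (cfg$nadir_sbp - cfg$baseline_sbp)) * noise_factor
  dbp <- (cfg$baseline_dbp + frac * (cfg$nadir_dbp - cfg$baseline_dbp)) * noise_factor
  # diastolic (end-diastolic) velocity ramps only below the reverse-onset SBP
  edv <- ifelse(
    sbp >= cfg$reverse_onset_sbp, cfg$baseline_edv,
    cfg$baseline_edv + (cfg$nadir_edv - cfg$baseline_edv) *
      pmin(1, (cfg$reverse_onset_sbp - sbp) / (cfg$reverse_onset_sbp - cfg$nadir_sbp)))
  list(map = map, sbp = sbp, dbp = dbp, edv = edv)
}

# shared engine: lay pulsatile beats over [0, total] given per-beat level
# functions; returns trace vectors plus the truth-beat table. waveform = FALSE
# computes only the beat table (identical RNG consumption in level_fun, so
# the per-beat truth is bit-identical to the rendered version).
render_pulsatile <- function(cfg, total_s, level_fun, tav_offset = 0,
                             waveform = TRUE) {
  fs <- cfg$fs
  n <- floor(total_s * fs)
  time_s <- seq_len(n) / fs - 1 / fs
  period <- 60 / cfg$heart_rate
  onsets <- seq(0, total_s - period, by = period)
  velocity <- numeric(n)
  pressure <- numeric(n)
  nb <- length(onsets)
  bv <- list(psv = numeric(nb), edv = numeric(nb), tav = numeric(nb),
             map = numeric(nb), sbp = numeric(nb), dbp = numeric(nb))
  ts <- cfg$systolic_frac * period
  tr <- cfg$reverse_frac * period
  for (b in seq_len(nb)) {
    lv <- level_fun(onsets[b])
    tav_b <- cfg$tav_map_intercept + cfg$tav_map_slope * lv$map +
      cfg$tav_map_quad * lv$map^2 + tav_offset
    rev_amp <- max(0, -lv$edv)
    A <- solve_systolic_amplitude(tav_b, lv$edv, rev_amp, period, ts, tr)
    A <- max(A, lv$edv + 5) # keep the template valid even in degenerate configs
    if (waveform) {
      tpl <- beat_template(A, ts, lv$edv, rev_amp, period, tr)
      idx <- which(time_s >= onsets[b] & time_s < onsets[b] + period)
      velocity[idx] <- gen_beat_waveform(tpl, time_s[idx] - onsets[b])
      # arterial pressure: raised-cosine systolic lobe over a diastolic base
      tb <- time_s[idx] - onsets[b]
      p <- rep(lv$dbp, length(idx))
      sys <- tb < ts
      p[sys] <- lv$dbp + (lv$sbp - lv$dbp) * 0.5 * (1 - cos(2 * pi * tb[sys] / ts))
      pressure[idx] <- p
    }
    bv$psv[b] <- A; bv$edv[b] <- lv$edv; bv$tav[b] <- tav_b
    bv$map[b] <- lv$map; bv$sbp[b] <- lv$sbp; bv$dbp[b] <- lv$dbp
  }
  beats <- tibble(
    beat_idx = seq_len(nb), t_start = onsets, t_end = onsets + period,
    psv = bv$psv, edv = bv$edv, tav = bv$tav,
    map = bv$map, sbp = bv$sbp, dbp = bv$dbp, hr = cfg$heart_rate)
  # past the last full beat, hold the final diastolic level
  tail_idx <- which(time_s >= onsets[nb] + period)
  if (waveform && length(tail_idx)) {
    velocity[tail_idx] <- bv$edv[nb]
    pressure[tail_idx] <- bv$dbp[nb]
  }
  list(time_s = time_s, velocity = velocity, pressure = pressure,
       onsets = onsets, beats = beats)
}

#' Simulate a vena cava occlusion (VCO) hypotension sequence
#'
#' A baseline hold (`lead_in_s`) followed by a linear decline of MAP, SBP and
#' DBP from their baseline values to their nadirs over `duration_s`, with
#' multiplicative beat-level noise on the pressure levels. Beat time-averaged
#' velocity follows the configured TAV~MAP coupling; once SBP falls below
#' `reverse_onset_sbp` the diastolic velocity ramps from its baseline value
#' down to `nadir_edv`, producing a growing early-diastolic reverse lobe
#' (high-resistance triphasic flow).
#'
#' @param cfg A [scenario_config()] with `kind = "vco"`.
#' @param seed Optional integer seed.
#' @param tav_offset Additive offset on the TAV coupling intercept, cm/s (used
#'   by [gen_study()] to inject animal/sequence random effects).
#' @param waveform Render the sampled velocity/pressure traces? With FALSE
#'   only the per-beat ground-truth table is produced (bit-identical to the
#'   rendered one), which is much faster for statistics-only studies.
#' @return A `scenario_traces` object: `$trace` (tibble `time_s`,
#'   `pressure_mmHg`, `velocity_cm_s`, `ecg_event`, `sync_pulse`), `$beats`
#'   (per-beat ground truth PSV/EDV/TAV/MAP/SBP/DBP), `$ecg_events`,
#'   `$sync_pulses`, `$segments`.
#' @examples
#' tr <- gen_vco_sequence(scenario_config("vco"), seed = 1)
#' min(tr$beats$sbp) # below 60 mmHg
#' @export
gen_vco_sequence <- function(cfg = scenario_config("vco"), seed = NULL,
                             tav_offset = 0, waveform = TRUE) {
  if (cfg$kind != "vco") stop_config("`cfg$kind` must be 'vco'")
  with_seed_opt(seed, {
    total <- cfg$lead_in_s + cfg$duration_s
    level_fun <- function(t_onset) {
      frac <- max(0, min(1, (t_onset - cfg$lead_in_s) / cfg$duration_s))
      nf <- if (cfg$map_noise_cv > 0 && frac > 0)
        1 + rnorm(1, 0, cfg$map_noise_cv) else 1
      vco_beat_levels(cfg, frac, nf)
    }
    rp <- render_pulsatile(cfg, total, level_fun, tav_offset,
                           waveform = waveform)
    sync <- gen_sync_channel(total, cfg$sync_interval_s, cfg$sync_jitter_sd)
    trace <- if (waveform) {
      velocity <- rp$velocity + rnorm(length(rp$velocity), 0, cfg$noise_sd)
      tibble(
        time_s = rp$time_s, pressure_mmHg = rp$pressure,
        velocity_cm_s = velocity,
        ecg_event = event_indicator(rp$time_s, rp$onsets),
        sync_pulse = event_indicator(rp$time_s, sync))
    } else {
      tibble(time_s = rp$time_s, pressure_mmHg = NA_real_,
             velocity_cm_s = NA_real_, ecg_event = 0L,
             sync_pulse = 0L)[0, ]
    }
    segments <- tibble(
      kind = c("baseline", "occlusion"),
      t_start = c(0, cfg$lead_in_s), t_end = c(cfg$lead_in_s, total))
    rp$beats$phase <- ifelse(rp$beats$t_start < cfg$lead_in_s,
                             "baseline", "occlusion")
    new_scenario_traces(trace, rp$beats, rp$onsets, sync, segments, cfg,
                        tav_offset)
  })
}

#' Simulate a ventricular fibrillation (VF) episode
#'
#' Pulsatile baseline flow until `vf_onset_s`; fibrillation onset appears as a
#' short broadband-noise marker on the velocity channel, after which pulsatile
#' flow ceases (zero-mean noise) and arterial pressure decays to a
#' non-pulsatile low value. ECG beat events stop at onset. After
#' `defib_delay_s` (never more than `vf_max_duration_s`, itself capped at
#' 60 s) defibrillation restores pulsatile flow and ECG events (ROSC).
#'
#' @param cfg A [scenario_config()] with `kind = "vf"`.
#' @param seed Optional integer seed.
#' @param n_episodes Number of consecutive episodes; onsets are spaced
#'   `vf_episode_interval_s` apart (default 300 s). `duration_s` must cover
#'   the last recovery phase.
#' @return A `scenario_traces` object; `$segments` flags `pulsatile`,
#'   `vf_marker` and `no_flow` intervals per episode.
#' @export
gen_vf_episode <- function(cfg = scenario_config("vf"), seed = NULL,
                           n_episodes = 1) {
  if (cfg$kind != "vf") stop_config("`cfg$kind` must be 'vf'")
  onset_times <- cfg$vf_onset_s + (seq_len(n_episodes) - 1) * cfg$vf_episode_interval_s
  if (n_episodes > 1 && max(onset_times) + cfg$defib_delay_s >= cfg$duration_s)
    stop_config("`duration_s` too short for the requested VF episodes")
  with_seed_opt(seed, {
    total <- cfg$duration_s
    level_fun <- function(t_onset) {
      list(map = cfg$baseline_map, sbp = cfg$baseline_sbp,
           dbp = cfg$baseline_dbp, edv = cfg$baseline_edv)
    }
    rp <- render_pulsatile(cfg, total, level_fun)
    velocity <- rp$velocity
    pressure <- rp$pressure
    time_s <- rp$time_s
    keep_beat <- rep(TRUE, nrow(rp$beats))
    seg <- list()
    t_prev_end <- 0
    for (on in onset_times) {
      rosc <- on + cfg$defib_delay_s
      marker_end <- min(on + cfg$vf_marker_s, rosc)
      im <- time_s >= on & time_s < marker_end
      io <- time_s >= marker_end & time_s < rosc
      velocity[im] <- rnorm(sum(im), 0, cfg$vf_marker_sd)
      velocity[io] <- 0 # arrest: the shared additive noise below remains
      # pressure collapses with ~1 s time constant, then sits non-pulsatile
      ia <- which(time_s >= on & time_s < rosc)
      p0 <- pressure[ia[1]]
      pressure[ia] <- cfg$vf_pressure +
        (p0 - cfg$vf_pressure) * exp(-(time_s[ia] - on) / 1) +
        rnorm(length(ia), 0, 0.3)
      # drop beats whose span intersects the arrest and re-time ECG
      keep_beat <- keep_beat &
        !(rp$beats$t_end > on & rp$beats$t_start < rosc)
      seg <- c(seg, list(tibble(
        kind = c("pulsatile", "vf_marker", "no_flow"),
        t_start = c(t_prev_end, on, marker_end),
        t_end = c(on, marker_end, rosc))))
      t_prev_end <- rosc
    }
    seg <- bind_rows(seg)
    seg <- bind_rows(seg, tibble(kind = "pulsatile",
                                 t_start = t_prev_end, t_end = total))
    beats <- rp$beats[keep_beat, , drop = FALSE]
    ecg <- beats$t_start
    velocity <- velocity + rnorm(length(velocity), 0, cfg$noise_sd)
    sync <- gen_sync_channel(total, cfg$sync_interval_s, cfg$sync_jitter_sd)
    trace <- tibble(
      time_s = time_s, pressure_mmHg = pressure, velocity_cm_s = velocity,
      ecg_event = event_indicator(time_s, ecg),
      sync_pulse = event_indicator(time_s, sync))
    new_scenario_traces(trace, beats, ecg, sync, seg, cfg)
  })
}

#' Simulate a true-PEA segment
#'
#' Organized ECG events continue at the configured heart rate while arterial
#' pressure sits near `pea_sbp` (default 20 mmHg systolic) and flow velocity
#' is low and near-pulseless around `pea_velocity` (default 10 cm/s) with at
#' most 20% ECG-locked amplitude modulation.
#'
#' @param cfg A [scenario_config()] with `kind = "pea"`.
#' @param seed Optional integer seed.
#' @return A `scenario_traces` object.
#' @export
gen_pea_segment <- function(cfg = scenario_config("pea"), seed = NULL) {
  if (cfg$kind != "pea") stop_config("`cfg$kind` must be 'pea'")
  with_seed_opt(seed, {
    total <- cfg$duration_s
    fs <- cfg$fs
    n <- floor(total * fs)
    time_s <- seq_len(n) / fs - 1 / fs
    period <- 60 / cfg$heart_rate
    onsets <- seq(0, total - period, by = period)
    ts <- cfg$systolic_frac * period
    phase <- (time_s %% period) / ts
    lobe <- ifelse(phase < 1, 0.5 * (1 - cos(2 * pi * phase)), 0)
    velocity <- cfg$pea_velocity * (1 + cfg$pea_modulation * (lobe - mean(lobe))) +
      rnorm(n, 0, cfg$noise_sd)
    pressure <- cfg$pea_dbp + (cfg$pea_sbp - cfg$pea_dbp) * lobe +
      rnorm(n, 0, 0.3)
    sync <- gen_sync_channel(total, cfg$sync_interval_s, cfg$sync_jitter_sd)
    beats <- tibble(
      beat_idx = seq_along(onsets), t_start = onsets, t_end = onsets + period,
      psv = cfg$pea_velocity * (1 + cfg$pea_modulation * (1 - mean(lobe))),
      edv = cfg$pea_velocity * (1 - cfg$pea_modulation * mean(lobe)),
      tav = cfg$pea_velocity,
      map = cfg$pea_dbp + (cfg$pea_sbp - cfg$pea_dbp) * mean(lobe),
      sbp = cfg$pea_sbp, dbp = cfg$pea_dbp, hr = cfg$heart_rate)
    trace <- tibble(
      time_s = time_s, pressure_mmHg = pressure, velocity_cm_s = velocity,
      ecg_event = event_indicator(time_s, onsets),
      sync_pulse = event_indicator(time_s, sync))
    segments <- tibble(kind = "pea", t_start = 0, t_end = total)
    new_scenario_traces(trace, beats, onsets, sync, segments, cfg)
  })
}
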