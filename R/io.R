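#' Write / read scenario traces as CSV
#'
#' The trace goes to `file` with columns `time_s`, `pressure_mmHg`,
#' `velocity_cm_s`, `ecg_event`, `sync_pulse`; the ground-truth beat table
#' goes to a companion CSV (default `<file stem>_beats.csv`). Numbers are
#' written at full double precision so a round trip is bit-identical.
#'
#' @param traces A `scenario_traces` object.
#' @param file Path of the trace CSV.
#' @param beats_file Path of the companion beat CSV.
#' @return `file`, invisibly.
#' @export
write_traces_csv <- function(traces, file,
                             beats_file = companion_path(file, "_beats")) {
  stopifnot(inherits(traces, "scenario_traces"))
  fwrite_full(traces$trace, file)
  fwrite_full(traces$beats, beats_file)
  invisible(file)
}

#' @rdname write_traces_csv
#' @param kind Scenario kind recorded in the rebuilt config.
#' @export
read_traces_csv <- function(file, beats_file = companion_path(file, "_beats"),
                            kind = "vco") {
  trace <- fread_tibble(file)
  need <- c("time_s", "pressure_mmHg", "velocity_cm_s", "ecg_event", "sync_pulse")
  if (!all(need %in% names(trace)))
    stop_data(paste("trace CSV must have columns:", paste(need, collapse = ", ")))
  beats <- fread_tibble(beats_file)
  fs <- 1 / median(diff(trace$time_s))
  cfg <- scenario_config(kind, duration_s = max(trace$time_s), fs = round(fs))
  new_scenario_traces(
    trace, beats,
    ecg_events = trace$time_s[trace$ecg_event == 1],
    sync_pulses = trace$time_s[trace$sync_pulse == 1],
    segments = tibble(kind = kind, t_start = 0, t_end = max(trace$time_s)),
    config = cfg)
}

companion_path <- function(file, suffix) {
  sub("(\\.[A-Za-z0-9]+)?$", paste0(suffix, ".csv"),
      sub("\\.csv$", "", file))
}

# full-precision CSV helpers: %.17g round-trips IEEE doubles exactly
fwrite_full <- function(df, file) {
  df2 <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  names(df2) <- names(df)
  data.table::fwrite(df2, file, quote = FALSE)
}

fread_tibble <- function(file) {
  if (!file.exists(file)) stop_data(sprintf("file not found: %s", file))
  out <- tryCatch(
    data.table::fread(file, data.table = FALSE, na.strings = c("NA")),
    error = function(e) stop_data(sprintf("malformed CSV %s: %s", file,
                                          conditionMessage(e))))
  as_tibble(out)
}

#' Write / read per-beat metrics CSV
#'
#' Columns `beat_idx`, `t_start`, `t_end`, `psv`, `edv`, `tav`, `ri`, `pi`,
#' `hr` and, when present, `tav2`, `alpha_deg`, `speed_cm_s`, `psv_corr`,
#' `edv_corr`. The `NaN` sentinel for an undefined pulsatility index
#' survives the round trip.
#'
#' @param metrics A `beat_metrics` tibble.
#' @param file Output path.
#' @export
write_metrics_csv <- function(metrics, file) {
  fwrite_full(metrics, file)
  invisible(file)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(file) {
  out <- fread_tibble(file)
  if (!all(c("beat_idx", "psv", "edv", "tav") %in% names(out)))
    stop_data("not a beat-metrics CSV")
  class(out) <- c("beat_metrics", class(out))
  out
}

#' Write / read a dual IQ record as a plain two-file container
#'
#' The record is stored as `<stem>.meta.json` (format version, acquisition
#' parameters, gate depths, vessel metadata, seed) plus `<stem>.iq.csv` with
#' long-format complex samples (`transducer`, `gate`, `sample`, `re`, `im`)
#' written at full double precision, so `read(write(x))` returns
#' bit-identical arrays.
#'
#' @param iq A `dual_iq_record`.
#' @param stem Path stem (no extension).
#' @return `stem`, invisibly.
#' @export
write_iq_record <- function(iq, stem) {
  stopifnot(inherits(iq, "dual_iq_record"))
  meta <- list(
    format = "pwdop-iq", version = 1L,
    prf = iq$prf, t0 = iq$t0,
    n_samples = nrow(iq$iq[[1]]), n_gates = ncol(iq$iq[[1]]),
    gate_depths_mm = iq$gate_depths_mm,
    geometry = unclass(iq$geometry), vessel = unclass(iq$vessel),
    snr_db = iq$snr_db, clutter_db = iq$clutter_db,
    n_scatterers = iq$n_scatterers, seed = iq$seed)
  jsonlite::write_json(meta, paste0(stem, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  n <- nrow(iq$iq[[1]]); ng <- ncol(iq$iq[[1]])
  long <- data.table::data.table(
    transducer = rep(1:2, each = n * ng),
    gate = rep(rep(seq_len(ng) - 1L, each = n), 2),
    sample = rep(seq_len(n) - 1L, 2 * ng),
    re = c(Re(iq$iq[[1]]), Re(iq$iq[[2]])),
    im = c(Im(iq$iq[[1]]), Im(iq$iq[[2]])))
  fwrite_full(long, paste0(stem, ".iq.csv"))
  invisible(stem)
}

#' @rdname write_iq_record
#' @export
read_iq_record <- function(stem) {
  meta_path <- paste0(stem, ".meta.json")
  iq_path <- paste0(stem, ".iq.csv")
  if (!file.exists(meta_path) || !file.exists(iq_path))
    stop_data(sprintf("IQ container incomplete at stem '%s'", stem))
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e) stop_data("malformed IQ metadata JSON"))
  if (!identical(meta$format, "pwdop-iq"))
    stop_data("not a pwdop IQ container")
  if (!identical(as.integer(meta$version), 1L))
    stop_data(sprintf("unsupported IQ container version %s", meta$version))
  long <- fread_tibble(iq_path)
  need <- c("transducer", "gate", "sample", "re", "im")
  if (!all(need %in% names(long)) ||
      nrow(long) != 2 * meta$n_samples * meta$n_gates)
    stop_data("IQ container truncated or malformed")
  iq <- lapply(1:2, function(k) {
    d <- long[long$transducer == k, ]
    d <- d[order(d$gate, d$sample), ]
    matrix(complex(real = d$re, imaginary = d$im), nrow = meta$n_samples)
  })
  geom <- do.call(probe_geometry, meta$geometry[c(
    "f0", "half_angle_deg", "n_gates", "gate_depth_min_mm",
    "gate_depth_max_mm", "prf", "c_sound")])
  ves <- do.call(vessel_model, meta$vessel)
  structure(
    list(iq = iq, prf = meta$prf, gate_depths_mm = meta$gate_depths_mm,
         t0 = meta$t0, geometry = geom, vessel = ves, snr_db = meta$snr_db,
         clutter_db = meta$clutter_db, n_scatterers = meta$n_scatterers,
         seed = meta$seed),
    class = "dual_iq_record")
}

#' Write / read results JSON
#'
#' @param x A named list (or coercible) of results.
#' @param file Output path.
#' @export
write_results_json <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(file)
}

#' @rdname write_results_json
#' @export
read_results_json <- function(file) {
  if (!file.exists(file)) stop_data(sprintf("file not found: %s", file))
  jsonlite::read_json(file, simplifyVector = TRUE)
}

#' Read a YAML run configuration
#'
#' Sections `probe`, `vessel`, `scenario`, `study`, `processing`, `stats`
#' are each optional; present sections are turned into the matching config
#' objects (unknown keys are rejected).
#'
#' @param file YAML path.
#' @return A list with the constructed config objects and raw lists for the
#'   `processing` / `stats` sections.
#' @export
read_config_yaml <- function(file) {
  if (!file.exists(file)) stop_data(sprintf("file not found: %s", file))
  raw <- tryCatch(yaml::read_yaml(file),
                  error = function(e) stop_config("malformed YAML config"))
  build <- function(section, fun) {
    if (is.null(raw[[section]])) return(NULL)
    args <- raw[[section]]
    ok <- names(args) %in% names(formals(fun))
    if (!all(ok))
      stop_config(sprintf("unknown %s keys: %s", section,
                          paste(names(args)[!ok], collapse = ", ")))
    do.call(fun, args)
  }
  list(
    probe = build("probe", probe_geometry),
    vessel = build("vessel", vessel_model),
    scenario = build("scenario", scenario_config),
    study = build("study", study_config),
    processing = raw$processing,
    stats = raw$stats)
}

#' Build and write a run manifest
#'
#' Records the seed, a hash of the configuration, package version, run
#' timestamps, and an md5 hash per output file, so a rerun with the same
#' manifest can be verified bit for bit.
#'
#' @param file Path the manifest JSON is written to.
#' @param seed Integer seed of the run.
#' @param config The configuration list the run used.
#' @param outputs Character vector of output file paths.
#' @param stage Stage name.
#' @return The manifest list, invisibly after writing.
#' @export
write_manifest <- function(file, seed, config, outputs, stage = "run") {
  hashes <- vapply(outputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_,
    character(1))
  manifest <- list(
    stage = stage, seed = seed,
    config_hash = unname(tools::md5sum(
      tmp <- local({
        f <- tempfile()
        jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                             force = TRUE)
        f
      }))),
    package_version = as.character(utils::packageVersion("pwdop")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(stats::setNames(hashes, outputs)))
  unlink(tmp)
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Align two sync-pulse clocks
#'
#' Matches pulses between the two channels by nearest neighbour (within half
#' the nominal spacing), then fits `t_b = offset + (1 + drift) * t_a` by
#' least squares with one pass of MAD-based outlier rejection.
#'
#' @param pulses_a,pulses_b Pulse times from the two recorders, s.
#' @param max_sep_s Maximum separation for a pulse match, s; default half
#'   the median spacing of `pulses_a`.
#' @return An object of class `clock_alignment`: `offset_s`, `drift_ppm`,
#'   `residual_rms_s`, `n_matched`.
#' @examples
#' align_clocks(0:19 * 6, 0:19 * 6 + 1.234)
#' @export
align_clocks <- function(pulses_a, pulses_b, max_sep_s = NULL) {
  if (length(pulses_a) < 3 || length(pulses_b) < 3)
    stop_data("need at least 3 pulses per channel")
  if (is.null(max_sep_s)) max_sep_s <- median(diff(sort(pulses_a))) / 2
  a <- sort(pulses_a); b <- sort(pulses_b)
  # coarse offset from median pairwise shift of the overlapping heads
  k <- min(length(a), length(b))
  coarse <- median(b[seq_len(k)] - a[seq_len(k)])
  idx <- vapply(a, function(t) {
    j <- which.min(abs(b - (t + coarse)))
    if (abs(b[j] - (t + coarse)) <= max_sep_s) j else NA_integer_
  }, integer(1))
  ok <- !is.na(idx)
  if (sum(ok) < 3) stop_data("fewer than 3 pulse matches; cannot align")
  x <- a[ok]; y <- b[idx[ok]]
  fit <- stats::lm(y ~ x)
  r <- stats::resid(fit)
  keep <- abs(r - median(r)) <= 3 * stats::mad(r) + 1e-12
  if (sum(keep) >= 3 && any(!keep)) fit <- stats::lm(y[keep] ~ x[keep])
  co <- coef(fit)
  structure(
    list(offset_s = unname(co[1]), drift_ppm = (unname(co[2]) - 1) * 1e6,
         residual_rms_s = sqrt(mean(stats::resid(fit)^2)),
         n_matched = sum(ok)),
    class = "clock_alignment")
}

#' @export
print.clock_alignment <- function(x, ...) {
  cat(sprintf(
    "<clock_alignment> offset %.4f s, drift %.1f ppm, residual RMS %.2e s (%d pulses)\n",
    x$offset_s, x$drift_ppm, x$residual_rms_s, x$n_matched))
  invisible(x)
}

#' @method tidy clock_alignment
#' @export
tidy.clock_alignment <- function(x, ...) {
  tibble(offset_s = x$offset_s, drift_ppm = x$drift_ppm,
         residual_rms_s = x$residual_rms_s, n_matched = x$n_matched)
}
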