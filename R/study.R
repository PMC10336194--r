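#' Study configuration: hierarchical multi-animal design
#'
#' Defines the hierarchical structure of a simulated study: animals with
#' nested repeated sequences, zero-mean Gaussian random intercepts at the
#' animal and sequence level, optional per-animal random slopes on MAP and
#' MAP^2, and residual observation noise on the 1-Hz TAV readings. Defaults
#' reproduce the study design the statistics stage targets: 7 animals with
#' sequence counts (6,6,6,6,6,6,5) = 41 sequences, intercept SDs chosen so
#' the variance decomposition is 88 : 6 : 6 (animal : sequence : residual),
#' i.e. intraclass correlations 0.88 (animal) and 0.94 (within animal).
#'
#' @param n_animals Number of animals. Default 7.
#' @param sequences_per_animal Integer vector of per-animal sequence counts;
#'   length must equal `n_animals`. Default `c(6,6,6,6,6,6,5)`.
#' @param animal_sd SD of the animal random intercept, cm/s. Default 9.381
#'   (`sqrt(88)`).
#' @param sequence_sd SD of the sequence-within-animal random intercept, cm/s.
#'   Default 2.449 (`sqrt(6)`).
#' @param residual_sd SD of the residual noise on each 1-Hz TAV observation,
#'   cm/s. Default 2.449.
#' @param slope_sd_map,slope_sd_map2 SDs of per-animal random slopes on MAP
#'   and MAP^2 (units cm/s per mmHg and per mmHg^2). Default 0.
#' @param fixed_beta Fixed coupling `(beta0, beta1, beta2)` of
#'   `TAV = beta0 + beta1*MAP + beta2*MAP^2`. Default `c(8.3, 0.333, 0)`.
#' @param duration_range_s Range the per-sequence occlusion durations are
#'   drawn from (uniform), s. Default `c(30, 69)`; draws are rescaled so the
#'   study mean duration is `duration_mean_s`.
#' @param duration_mean_s Target mean occlusion duration, s. Default 50.
#' @param level_jitter Logical; draw per-sequence baseline/nadir pressure
#'   levels around the scenario config values with the observed between-
#'   sequence SDs (clamped to the observed ranges)? Default TRUE.
#' @param seed Optional integer root seed; per-sequence child streams are
#'   derived from it so the dataset is reproducible.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_animals = 7,
                         sequences_per_animal = c(6, 6, 6, 6, 6, 6, 5),
                         animal_sd = 9.381, sequence_sd = 2.449,
                         residual_sd = 2.449,
                         slope_sd_map = 0, slope_sd_map2 = 0,
                         fixed_beta = c(8.3, 0.333, 0),
                         duration_range_s = c(30, 69), duration_mean_s = 50,
                         level_jitter = TRUE,
                         seed = NULL) {
  if (length(sequences_per_animal) != n_animals)
    stop_config("`sequences_per_animal` must have length `n_animals`")
  if (any(sequences_per_animal < 1))
    stop_config("each animal needs at least one sequence")
  if (any(c(animal_sd, sequence_sd, residual_sd, slope_sd_map, slope_sd_map2) < 0))
    stop_config("all SDs must be >= 0")
  if (length(fixed_beta) != 3)
    stop_config("`fixed_beta` must be (beta0, beta1, beta2)")
  structure(as.list(environment()), class = "study_config")
}

# between-sequence variation of the pressure anchors (level SD and allowed
# range per anchor); used when `level_jitter` is on
study_level_jitter_spec <- function() {
  list(
    baseline_map = list(sd = 11.4, lo = 66, hi = 106),
    baseline_sbp = list(sd = 12.9, lo = 86, hi = 133),
    baseline_dbp = list(sd = 9.6, lo = 45, hi = 81),
    nadir_map = list(sd = 5.5, lo = 12, hi = 33),
    nadir_sbp = list(sd = 7.8, lo = 19, hi = 46),
    nadir_dbp = list(sd = 5.4, lo = 8, hi = 27))
}

child_seed <- function(root, k) as.integer((as.numeric(root) * 10007 + 17 * k) %% 2147483629)

#' Generate a hierarchical multi-animal VCO study
#'
#' Draws animal and sequence random effects, generates one VCO sequence per
#' (animal, sequence) with those effects added to the TAV~MAP coupling, and
#' emits a long-format observation table sampled at 1 Hz with residual noise
#' on TAV — the input the statistics stage expects.
#'
#' @param study A [study_config()].
#' @param scenario A [scenario_config()] with `kind = "vco"` used as the base
#'   for every sequence.
#' @param seed Integer root seed; overrides `study$seed` when given.
#' @param keep_traces Render and keep the full `scenario_traces` objects
#'   (memory-heavy for large studies)? With FALSE only the per-beat truth and
#'   the 1-Hz table are computed; both are bit-identical to the rendered
#'   run's. Default TRUE.
#' @return An object of class `study_dataset`: `$table` (tibble `animal`,
#'   `sequence`, `t_s`, `map`, `tav`), `$sequences` (named list of
#'   `scenario_traces`, if kept), `$effects` (true per-animal/sequence random
#'   effects), `$config`.
#' @examples
#' st <- gen_study(study_config(n_animals = 2, sequences_per_animal = c(2, 2)),
#'                 seed = 1, keep_traces = FALSE)
#' dplyr::count(st$table, animal)
#' @export
gen_study <- function(study = study_config(),
                      scenario = scenario_config("vco"),
                      seed = NULL, keep_traces = TRUE) {
  if (scenario$kind != "vco")
    stop_config("study generation currently supports `kind = 'vco'` scenarios")
  seed <- seed %||% study$seed
  if (is.null(seed))
    stop_config("`seed` is required (set it here or in `study_config()`)")
  seed <- as.integer(seed)
  na <- study$n_animals
  nseq <- study$sequences_per_animal
  jit <- study_level_jitter_spec()

  eff <- with_seed_opt(seed, {
    tibble(
      animal = paste0("a", seq_len(na)),
      intercept = rnorm(na, 0, study$animal_sd),
      slope_map = rnorm(na, 0, study$slope_sd_map),
      slope_map2 = rnorm(na, 0, study$slope_sd_map2))
  })
  seq_eff <- with_seed_opt(child_seed(seed, 1L), {
    tibble(
      animal = rep(eff$animal, nseq),
      sequence = unlist(lapply(seq_len(na), function(i)
        paste0("a", i, "_s", seq_len(nseq[i])))),
      seq_intercept = rnorm(sum(nseq), 0, study$sequence_sd))
  })
  n_total <- sum(nseq)
  durations <- with_seed_opt(child_seed(seed, 2L), {
    u <- runif(n_total, study$duration_range_s[1], study$duration_range_s[2])
    u * study$duration_mean_s / mean(u)
  })
  levels_draw <- with_seed_opt(child_seed(seed, 3L), {
    draws <- lapply(names(jit), function(nm) {
      s <- jit[[nm]]
      if (study$level_jitter)
        pmin(pmax(rnorm(n_total, scenario[[nm]], s$sd), s$lo), s$hi)
      else rep(scenario[[nm]], n_total)
    })
    names(draws) <- names(jit)
    draws
  })
  # keep each sequence's nadir strictly below baseline and below 60 mmHg SBP
  levels_draw$nadir_sbp <- pmin(levels_draw$nadir_sbp, 59,
                                levels_draw$baseline_sbp - 10)
  levels_draw$nadir_map <- pmin(levels_draw$nadir_map,
                                levels_draw$baseline_map - 10)
  levels_draw$nadir_dbp <- pmin(levels_draw$nadir_dbp,
                                levels_draw$baseline_dbp - 10)

  sequences <- vector("list", n_total)
  tables <- vector("list", n_total)
  for (k in seq_len(n_total)) {
    an <- seq_eff$animal[k]
    a_row <- eff[eff$animal == an, ]
    cfg_k <- scenario
    cfg_k$duration_s <- durations[k]
    for (nm in names(jit)) cfg_k[[nm]] <- levels_draw[[nm]][k]
    # random effects enter the coupling: intercept shift + per-animal slopes
    cfg_k$tav_map_slope <- scenario$tav_map_slope + a_row$slope_map
    cfg_k$tav_map_quad <- scenario$tav_map_quad + a_row$slope_map2
    offset_k <- a_row$intercept + seq_eff$seq_intercept[k]
    tr <- gen_vco_sequence(cfg_k, seed = child_seed(seed, 10L + k),
                           tav_offset = offset_k, waveform = keep_traces)
    # 1-Hz observation table: realized per-beat MAP interpolated to seconds,
    # TAV recomputed from the same MAP through the sequence's coupling,
    # residual noise added per reading
    t_sec <- seq(0, floor(max(tr$beats$t_end)))
    map_sec <- approx(tr$beats$t_start, tr$beats$map, xout = t_sec, rule = 2)$y
    tav_sec <- cfg_k$tav_map_intercept + cfg_k$tav_map_slope * map_sec +
      cfg_k$tav_map_quad * map_sec^2 + offset_k
    resid <- with_seed_opt(child_seed(seed, 100000L + k),
                           rnorm(length(t_sec), 0, study$residual_sd))
    tables[[k]] <- tibble(
      animal = an, sequence = seq_eff$sequence[k],
      t_s = t_sec, map = map_sec, tav = tav_sec + resid)
    if (keep_traces) sequences[[k]] <- tr
  }
  names(sequences) <- seq_eff$sequence
  structure(
    list(table = bind_rows(tables),
         sequences = if (keep_traces) sequences else NULL,
         effects = list(animal = eff, sequence = seq_eff,
                        durations = durations),
         study = study, scenario = scenario, seed = seed),
    class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "<study_dataset> %d animals, %d sequences, %d observations at 1 Hz\n",
    x$study$n_animals, sum(x$study$sequences_per_animal), nrow(x$table)))
  invisible(x)
}

#' @method as_tibble study_dataset
#' @export
as_tibble.study_dataset <- function(x, ...) x$table
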