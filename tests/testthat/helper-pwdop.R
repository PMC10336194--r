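# shared fixtures: short, cheap configurations used across test files

short_vco <- function(...) scenario_config("vco", duration_s = 12,
                                           lead_in_s = 4, ...)

# deterministic VCO without beat-level or sample noise (overridable)
clean_vco <- function(...) {
  args <- utils::modifyList(list(kind = "vco", noise_sd = 0, map_noise_cv = 0),
                            list(...))
  do.call(scenario_config, args)
}

# a tiny study design that still satisfies the fit preconditions
tiny_study <- function(...) study_config(n_animals = 3,
                                         sequences_per_animal = c(2, 2, 2),
                                         ...)

# constant-velocity traces (for spectral oracles): reuse a generated VCO
# container but overwrite the velocity channel
const_traces <- function(v_cm_s, duration_s = 3) {
  tr <- gen_vco_sequence(clean_vco(), seed = 1)
  tr$trace <- tr$trace[tr$trace$time_s < duration_s, ]
  tr$trace$velocity_cm_s <- rep(v_cm_s, nrow(tr$trace))
  tr
}

# synthesize + process one scenario with given inclination; returns list
run_chain <- function(traces, alpha_deg = 0, snr_db = 20, seed = 11, ...) {
  iq <- synthesize_iq(traces, probe_geometry(),
                      vessel_model(inclination_deg = alpha_deg),
                      snr_db = snr_db, seed = seed, ...)
  process_dual_iq(iq, ecg_events = traces$ecg_events)
}

# mean-velocity of one gate/transducer from a colour M-mode
mmode_gate_velocity <- function(mm, trans, gate) {
  mm$mean_velocity[mm$transducer == trans & mm$gate == gate]
}

# a fake lmm_fit carrying prescribed variance components (for the analytic
# ICC identities, which do not depend on an actual model fit)
fake_fit <- function(va, vs, ve) {
  structure(
    list(components = tibble::tibble(
           component = c("animal", "sequence", "residual"),
           variance = c(va, vs, ve)),
         method = "REML", random_slopes = FALSE),
    class = "lmm_fit")
}
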