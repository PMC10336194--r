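geom <- probe_geometry()

test_that("a centreline scatterer produces the Doppler-equation tone", {
  tr <- const_traces(38.5)
  for (alpha in c(-20, 0, 20)) {
    iq <- synthesize_iq(tr, geom, vessel_model(inclination_deg = alpha),
                        snr_db = Inf, clutter_db = -Inf, n_scatterers = 1,
                        scatterer_placement = "centerline", seed = 2)
    for (k in 1:2) {
      phi <- (alpha + c(-30, 30)[k]) * pi / 180
      f_expect <- 2 * geom$f0 * 0.385 * cos(phi) / geom$c_sound
      sp <- compute_spectrogram(iq$iq[[k]][, 13], prf = geom$prf)
      pk_v <- sp$velocity[which.max(sp$power[, 10])]
      f_meas <- pk_v / 100 * 2 * geom$f0 / geom$c_sound
      expect_lt(abs(f_meas - f_expect), geom$prf / nrow(sp$power) + 1e-9)
    }
  }
})

test_that("flow-band energy is localized to gates intersecting the lumen", {
  tr <- const_traces(40, duration_s = 2)
  iq <- synthesize_iq(tr, geom, vessel_model(), snr_db = 20, seed = 3)
  iqf <- wall_filter(iq)
  # above-noise flow-band power per gate: spectrogram bins beyond
  # slow-tissue velocities, thresholded at the same 8-dB margin over the
  # per-frame noise floor that the envelope tracer treats as signal
  band_pw <- vapply(seq_len(geom$n_gates), function(g) {
    sp <- compute_spectrogram(iqf$iq[[1]][, g], prf = geom$prf)
    thr <- apply(sp$power, 2, median) * 10^(8 / 10)
    above <- sweep(sp$power, 2, thr, "-")
    above[above < 0] <- 0
    sum(above[abs(sp$velocity) > 5, ])
  }, numeric(1))
  in_lumen <- abs(iq$gate_depths_mm - 22) < 2.5
  expect_gte(sum(band_pw[in_lumen]) / sum(band_pw), 0.90)
})

test_that("zero flow leaves only clutter and noise", {
  tr <- const_traces(0)
  iq <- synthesize_iq(tr, geom, vessel_model(), snr_db = 20, seed = 4)
  iqf <- wall_filter(iq)
  pw <- colMeans(pwdop:::Mag2(iqf$iq[[1]]))
  # post-wall-filter power in lumen gates comparable to non-lumen (noise floor)
  in_lumen <- abs(iq$gate_depths_mm - 22) < 2.5
  expect_lt(mean(pw[in_lumen]) / mean(pw[!in_lumen]), 3)
})

test_that("transducer asymmetry follows the cosine projection ratio", {
  tr <- const_traces(40, duration_s = 4)
  alpha <- 10
  iq <- synthesize_iq(tr, geom, vessel_model(inclination_deg = alpha),
                      snr_db = 30, seed = 5)
  iqf <- wall_filter(iq)
  mm <- compute_color_mmode(iqf)
  v1 <- mean(abs(mmode_gate_velocity(mm, 1, 12)))
  v2 <- mean(abs(mmode_gate_velocity(mm, 2, 12)))
  expect_equal(v1 / v2, cos((alpha - 30) * pi / 180) / cos((alpha + 30) * pi / 180),
               tolerance = 0.05)
})

test_that("synthesis is deterministic per seed", {
  tr <- const_traces(30, duration_s = 1.5)
  a <- synthesize_iq(tr, geom, vessel_model(), seed = 6)
  b <- synthesize_iq(tr, geom, vessel_model(), seed = 6)
  expect_identical(a$iq, b$iq)
})

test_that("aliasing velocities are refused when requested", {
  tr <- const_traces(250) # 250 cm/s exceeds Nyquist at PRF 15 kHz
  expect_error(
    synthesize_iq(tr, geom, vessel_model(), seed = 7, alias = "refuse"),
    class = "pwdop_data_error")
  expect_warning(
    synthesize_iq(const_traces(250, duration_s = 1.2), geom, vessel_model(),
                  seed = 7, alias = "warn"))
})
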