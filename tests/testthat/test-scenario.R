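test_that("sync channel produces evenly spaced pulses", {
  s <- gen_sync_channel(60)
  expect_length(s, 11) # ten 6-s intervals
  expect_true(all(diff(s) == 6))
  expect_equal(gen_sync_channel(3, 6), 0) # shorter than one interval
  # jittered pulse spacing has SD sqrt(2) * jitter_sd
  sj <- gen_sync_channel(6000, 6, jitter_sd = 0.01, seed = 5)
  expect_equal(sd(diff(sj)), sqrt(2) * 0.01, tolerance = 0.1)
  expect_error(gen_sync_channel(10, 0), class = "pwdop_config_error")
})

test_that("VCO sequences terminate below 60 mmHg systolic for any seed", {
  for (s in 1:5) {
    tr <- gen_vco_sequence(scenario_config("vco"), seed = s)
    expect_lt(min(tr$beats$sbp), 60)
  }
})

test_that("reverse flow appears only below the reverse-onset pressure", {
  tr <- gen_vco_sequence(clean_vco(), seed = 2)
  b <- tr$beats
  expect_true(all(b$edv[b$sbp > 80] >= 0))
  # minimum of the (noise-free) velocity trace while SBP > 80 is >= 0
  t_high <- b$t_end[max(which(b$sbp > 80))]
  expect_gte(min(tr$trace$velocity_cm_s[tr$trace$time_s < t_high]), -1e-9)
  # ... and the final beats do reverse
  expect_lt(tail(b$edv, 1), 0)
})

test_that("noise-free TAV coupling matches the configured line", {
  tr <- gen_vco_sequence(clean_vco(), seed = 1)
  b <- tr$beats
  expect_equal(b$tav, 8.3 + 0.333 * b$map, tolerance = 1e-12)
  expect_equal(b$tav[1], 8.3 + 0.333 * 86) # 36.938 at baseline MAP 86
  # beat waveform time-average reproduces the coupled TAV (closed form)
  k <- 5
  idx <- tr$trace$time_s >= b$t_start[k] & tr$trace$time_s < b$t_end[k]
  expect_equal(mean(tr$trace$velocity_cm_s[idx]), b$tav[k], tolerance = 0.02)
})

test_that("noise-free MAP declines monotonically after the lead-in", {
  tr <- gen_vco_sequence(clean_vco(), seed = 1)
  occl <- tr$beats[tr$beats$phase == "occlusion", ]
  expect_true(all(diff(occl$map) <= 1e-9))
})

test_that("identical seeds give bit-identical sequences", {
  a <- gen_vco_sequence(scenario_config("vco"), seed = 7)
  b <- gen_vco_sequence(scenario_config("vco"), seed = 7)
  expect_identical(a$trace, b$trace)
  expect_identical(a$beats, b$beats)
})

test_that("VF episodes silence beat-locked velocity oscillation until ROSC", {
  cfg <- scenario_config("vf", vf_onset_s = 10, defib_delay_s = 15,
                         duration_s = 40)
  tr <- gen_vf_episode(cfg, seed = 3)
  v <- tr$trace$velocity_cm_s
  t <- tr$trace$time_s
  # arrest interval past the broadband marker: zero-mean noise only
  arrest <- t > 11.6 & t < 24.9
  expect_lt(sd(v[arrest]), 3 * cfg$noise_sd)
  expect_lt(abs(mean(v[arrest])), 1)
  # beat-locked variance: fold arrest samples at the cardiac period
  phase <- (t[arrest] %% (60 / cfg$heart_rate))
  folded <- tapply(v[arrest], cut(phase, 10), mean)
  expect_lt(var(folded), cfg$noise_sd^2) # no coherent beat shape
  # pulsatile before onset and after ROSC
  expect_gt(max(v[t < 10]), 50)
  expect_gt(max(v[t > 26]), 50)
  # ECG events stop at onset and resume at ROSC
  expect_false(any(tr$ecg_events > 10.6 & tr$ecg_events < 24.9))
  expect_true(any(tr$ecg_events > 25))
  # pressure non-pulsatile and low once the ~1-s collapse has run its course
  settled <- t > 14 & t < 24.9
  expect_lt(max(tr$trace$pressure_mmHg[settled]), 20)
  expect_lt(sd(tr$trace$pressure_mmHg[settled]), 1)
})

test_that("defibrillation is never later than the untreated-VF cap", {
  cfg <- scenario_config("vf")
  expect_lte(cfg$defib_delay_s, 60)
  expect_error(scenario_config("vf", defib_delay_s = 70),
               class = "pwdop_config_error")
  expect_error(scenario_config("vf", vf_max_duration_s = 80),
               class = "pwdop_config_error")
})

test_that("consecutive VF episodes are spaced five minutes apart", {
  cfg <- scenario_config("vf", vf_onset_s = 15, defib_delay_s = 20,
                         duration_s = 360)
  tr <- gen_vf_episode(cfg, seed = 4, n_episodes = 2)
  onsets <- tr$segments$t_start[tr$segments$kind == "vf_marker"]
  expect_equal(diff(onsets), 300)
})

test_that("true PEA keeps organized ECG with ~20 mmHg pressure and ~10 cm/s flow", {
  tr <- gen_pea_segment(scenario_config("pea"), seed = 5)
  expect_equal(max(tr$trace$pressure_mmHg), 20, tolerance = 0.15)
  expect_equal(mean(abs(tr$trace$velocity_cm_s)), 10, tolerance = 0.1)
  expect_gt(length(tr$ecg_events), 40) # organized rhythm continues
  # near-pulseless: modulation bounded
  v <- tr$trace$velocity_cm_s
  expect_lt(max(v) - min(v), 0.5 * 10 + 8 * tr$config$noise_sd)
  # zero-velocity PEA degenerates to noise about zero
  tr0 <- gen_pea_segment(scenario_config("pea", pea_velocity = 0), seed = 5)
  expect_lt(abs(mean(tr0$trace$velocity_cm_s)), 0.5)
})

test_that("scenario config rejects impossible settings", {
  expect_error(scenario_config("vco", nadir_map = 90),
               class = "pwdop_config_error")
  expect_error(scenario_config("vco", nadir_sbp = 65),
               class = "pwdop_config_error")
  expect_error(scenario_config("vf", vf_onset_s = 100, duration_s = 50),
               class = "pwdop_config_error")
  expect_error(scenario_config("pea", pea_modulation = 0.5),
               class = "pwdop_config_error")
})
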