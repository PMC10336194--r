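prf <- 15000

test_that("wall filter rejects DC and preserves the passband", {
  n <- 30000
  t <- seq_len(n) / prf
  mid <- 2000:28000
  dc <- rep(1 + 0i, n)
  expect_lt(mean(Mod(wall_filter(dc, 100, prf = prf)[mid])^2), 1e-4)
  tone <- exp(2i * pi * 2000 * t)
  gain_db <- 10 * log10(mean(Mod(wall_filter(tone, 100, prf = prf)[mid])^2))
  expect_lt(abs(gain_db), 1)
  expect_equal(wall_filter(rep(0 + 0i, 1000), 100, prf = prf),
               rep(0 + 0i, 1000))
  expect_error(wall_filter(dc, 5000, prf = prf), class = "pwdop_config_error")
})

test_that("spectrogram maps a known tone to the right velocity bin", {
  t <- seq_len(3 * prf) / prf
  f_d <- 1732
  sp <- compute_spectrogram(exp(2i * pi * f_d * t), prf = prf)
  v_expect <- 1540 * f_d / (2 * 4e6) * 100 # 33.3 cm/s axial
  pk <- sp$velocity[apply(sp$power, 2, which.max)]
  expect_lt(max(abs(pk - v_expect)), sp$bin_cm_s + 1e-9)
  # negative-frequency tone lands on the negative half axis
  spn <- compute_spectrogram(exp(-2i * pi * f_d * t), prf = prf)
  pkn <- spn$velocity[apply(spn$power, 2, which.max)]
  expect_true(all(pkn < 0))
  expect_error(compute_spectrogram(exp(2i * pi * f_d * t[1:100]), prf = prf),
               class = "pwdop_data_error")
})

test_that("white-noise spectrum is flat within 3 dB", {
  set.seed(8)
  n <- 8 * prf
  x <- complex(real = rnorm(n), imaginary = rnorm(n))
  sp <- compute_spectrogram(x, prf = prf)
  band_db <- 10 * log10(rowMeans(sp$power))
  expect_lt(max(band_db) - min(band_db), 3)
})

test_that("autocorrelation mean velocity is exact for noise-free tones", {
  t <- seq_len(prf) / prf
  f_d <- 2000
  mm <- compute_color_mmode(matrix(exp(2i * pi * f_d * t), ncol = 1),
                            prf = prf)
  v_expect <- 1540 * f_d / (2 * 4e6) * 100
  expect_equal(mean(mm$mean_velocity), v_expect, tolerance = 1e-6)
  # beyond Nyquist the estimate wraps to negative velocities
  mma <- compute_color_mmode(matrix(exp(2i * pi * 9000 * t), ncol = 1),
                             prf = prf)
  expect_true(all(mma$mean_velocity < 0))
  # zero signal: power 0 and velocity 0 by convention
  mm0 <- compute_color_mmode(matrix(0 + 0i, nrow = prf, ncol = 1), prf = prf)
  expect_true(all(mm0$power == 0))
  expect_true(all(mm0$mean_velocity == 0))
})

test_that("spectrogram first moment agrees with the autocorrelation estimate", {
  set.seed(9)
  tr <- const_traces(35, duration_s = 2)
  iq <- synthesize_iq(tr, probe_geometry(), vessel_model(), snr_db = 25,
                      seed = 10)
  iqf <- wall_filter(iq)
  x <- iqf$iq[[1]][, 13]
  sp <- compute_spectrogram(x, prf = prf)
  w <- sweep(sp$power, 2, colSums(sp$power), "/")
  vbar_spec <- mean(colSums(w * sp$velocity))
  mm <- compute_color_mmode(matrix(x, ncol = 1), prf = prf)
  expect_equal(vbar_spec, mean(mm$mean_velocity), tolerance = 0.05 * abs(vbar_spec))
})

test_that("gate selection finds the vessel and flags flow-free records", {
  tr <- const_traces(40, duration_s = 3)
  # make it pulsatile so the 0.5-4 Hz band carries energy
  tr$trace$velocity_cm_s <- 40 + 25 * sin(2 * pi * 1.5 * tr$trace$time_s)
  iq <- synthesize_iq(tr, probe_geometry(), vessel_model(), snr_db = 20,
                      seed = 11)
  sel <- select_gate(compute_color_mmode(wall_filter(iq)))
  expect_true(all(abs(sel$depth_mm - 22) <= 1.3)) # within one gate spacing
  # clutter + noise only: no-flow sentinel
  iq0 <- synthesize_iq(const_traces(0, duration_s = 2), probe_geometry(),
                       vessel_model(), snr_db = 20, seed = 12)
  sel0 <- select_gate(compute_color_mmode(wall_filter(iq0)))
  expect_true(all(is.na(sel0$gate)))
})

test_that("envelope tracks a noise-free tone and flags pure noise", {
  t <- seq_len(2 * prf) / prf
  sp <- compute_spectrogram(exp(2i * pi * 1732 * t), prf = prf)
  env <- trace_envelope(sp)
  expect_equal(median(env$v_max), 33.3, tolerance = 2 * sp$bin_cm_s)
  expect_true(all(env$quality == "ok"))
  set.seed(13)
  spn <- compute_spectrogram(
    complex(real = rnorm(prf), imaginary = rnorm(prf)), prf = prf)
  envn <- trace_envelope(spn)
  expect_gt(mean(envn$quality == "low"), 0.9)
  expect_equal(median(abs(envn$v_max)), 0, tolerance = 1e-9)
})

test_that("envelope goes negative during reverse diastolic flow", {
  cfg <- clean_vco(duration_s = 8, lead_in_s = 0, noise_sd = 1)
  tr <- gen_vco_sequence(cfg, seed = 14)
  # end of the ramp: strong reverse lobe
  iq <- synthesize_iq(tr, probe_geometry(), vessel_model(), snr_db = 25,
                      seed = 15)
  iqf <- wall_filter(iq)
  sp <- compute_spectrogram(iqf$iq[[1]][, 13], prf = prf)
  env <- trace_envelope(sp)
  late <- env$v_max[env$t > 6.5]
  expect_lt(min(late), -10) # reverse flow is first-class, signed
})

test_that("beat detection recovers simulated beats and their rate", {
  cfg <- clean_vco(heart_rate = 75, duration_s = 8, lead_in_s = 0,
                   noise_sd = 0.5)
  tr <- gen_vco_sequence(cfg, seed = 16)
  env <- as_envelope(tr)
  beats <- detect_beats(env)
  # every interior beat is found; the first/last need a flanking peak
  expect_gte(nrow(beats), nrow(tr$beats) - 2)
  expect_lte(nrow(beats), nrow(tr$beats))
  # detected onsets sit on the simulated beat grid
  near <- vapply(beats$t_start, function(t0)
    min(abs(t0 - tr$beats$t_start)), numeric(1))
  expect_lt(max(near), 0.15)
  m <- compute_beat_metrics(env, beats)
  expect_equal(mean(m$hr), 75, tolerance = 2 / 75)
  # flat envelope: no beats
  flat <- env
  flat$v_max <- rep(20, nrow(flat))
  expect_equal(nrow(detect_beats(flat)), 0)
})

test_that("beat metrics match closed forms on a rectangular beat", {
  t <- seq(0, 2.4, by = 0.002)
  v <- ifelse(t %% 0.8 < 0.2, 100, 20)
  env <- tibble::tibble(t = t, v_max = v, quality = "ok")
  beats <- tibble::tibble(beat_idx = 1L,
                          t_start = 0.8, t_end = 1.6,
                          i_start = which.min(abs(t - 0.8)),
                          i_end = which.min(abs(t - 1.6)))
  m <- compute_beat_metrics(env, beats)
  expect_equal(m$psv, 100)
  expect_equal(m$edv, 20)
  expect_equal(m$tav, 40, tolerance = 0.01)
  expect_equal(m$ri, 0.8, tolerance = 1e-3)
  expect_equal(m$pi, 2.0, tolerance = 0.01)
  expect_equal(m$hr, 75, tolerance = 1e-6)
})

test_that("index formulas handle constant and reverse-flow beats", {
  t <- seq(0, 3, by = 0.01)
  env <- tibble::tibble(t = t, v_max = rep(30, length(t)), quality = "ok")
  beats <- tibble::tibble(beat_idx = 1L, t_start = 1, t_end = 2,
                          i_start = 101L, i_end = 201L)
  m <- compute_beat_metrics(env, beats)
  expect_equal(m$ri, 0)
  expect_equal(m$pi, 0)
  # the low-pressure mean values: PSV 73, EDV -29, TAV 16
  ri <- (73 - (-29)) / 73
  pi_ <- (73 - (-29)) / 16
  expect_equal(ri, 1.397, tolerance = 1e-3)
  expect_equal(pi_, 6.375, tolerance = 1e-3)
  # a zero-TAV beat yields the NaN sentinel for PI
  env0 <- tibble::tibble(t = t, v_max = c(rep(0, 150), rep(0, length(t) - 150)),
                         quality = "ok")
  m0 <- compute_beat_metrics(env0, beats)
  expect_true(is.nan(m0$pi))
})

test_that("angle inversion is exact on worked cases and round-trips", {
  a <- estimate_angle(40, 20)
  expect_equal(a$alpha_deg, 30, tolerance = 1e-9)
  expect_equal(a$speed, 40, tolerance = 1e-9)
  sym <- estimate_angle(34.641, 34.641)
  expect_equal(sym$alpha_deg, 0, tolerance = 1e-9)
  expect_equal(sym$speed, 34.641 / cos(pi / 6), tolerance = 1e-6)
  # dense round-trip grid
  for (v in c(5.5, 20, 50, 100, 149)) {
    for (alpha in seq(-39, 39, by = 3)) {
      t1 <- v * cos((alpha - 30) * pi / 180)
      t2 <- v * cos((alpha + 30) * pi / 180)
      est <- estimate_angle(t1, t2)
      expect_equal(est$alpha_deg, alpha, tolerance = 1e-9)
      expect_equal(est$speed, v, tolerance = 1e-9 * v)
    }
  }
  expect_error(estimate_angle(10, -10), class = "pwdop_data_error")
})
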