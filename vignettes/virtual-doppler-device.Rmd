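---
title: "A virtual dual-transducer carotid Doppler device: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual dual-transducer carotid Doppler device}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pwdop` is a software twin of a hands-free carotid pulse-monitoring system:
two pulsed-wave Doppler transducers fixed in a casing at ±30° interrogate the
common carotid artery at 32 range gates, and the processing chain turns the
returned echoes into beat-wise hemodynamic indices and a pulse/no-pulse
decision. Because the animal recordings such systems are validated on cannot
be redistributed, the package pairs the measurement chain with a calibrated
scenario simulator, so every stage is testable end to end from first
principles. This vignette describes the models, their assumptions, the
parameters that matter, and the design decisions taken where the problem was
genuinely open.

## The scenario simulator

### Beat waveform

A cardiac cycle of centreline blood velocity is modelled as a raised-cosine
systolic lobe of duration `systolic_frac * period`, an optional raised-cosine
reverse lobe in early diastole (high-resistance triphasic flow, as seen in
the porcine carotid), and a constant diastolic tail whose value is the
end-diastolic velocity (EDV). The template integrates in closed form, so the
systolic amplitude needed to hit a prescribed time-averaged velocity (TAV)
is solved exactly; the closed form is also the oracle the tests integrate
against numerically.

One consequence is worth stating plainly: a two-lobe template cannot match a
prescribed PSV, TAV and EDV simultaneously. The simulator treats TAV and EDV
as the calibrated quantities (they anchor the hypotension study) and lets
peak systolic velocity float; at deep hypotension the solved systolic
amplitude is higher than the peaks a real carotid shows at the same TAV,
because real diastole is not a flat tail. Tests compare pipeline PSV against
the *generator's* truth, which is self-consistent; PSV is deliberately not a
calibration anchor.

### Vena cava occlusion (VCO)

A VCO sequence is a 10-s baseline hold followed by a linear decline of MAP
(86 to 23 mmHg), SBP (111 to 33) and DBP (66 to 18) over the occlusion
(default 50 s), with multiplicative beat-level noise (CV 2%) on the pressure
levels. Whether the physiological decline is linear or exponential in time
is not recoverable from published traces; linear was chosen as the simplest
monotone ramp and is configurable by editing the per-beat level function.
Beat TAV follows the coupling `TAV = 8.3 + 0.333 * MAP` (cm/s, mmHg), chosen
so TAV is about 37 cm/s at baseline MAP 86 and about 16 cm/s at MAP 23; a
quadratic term exists but defaults to zero. Below an SBP of 80 mmHg the
diastolic velocity ramps from +10 cm/s down to −29 cm/s at the nadir, which
makes the reverse lobe grow smoothly; above 80 mmHg there is no reverse
flow. The termination rule (nadir SBP below 60 mmHg) is enforced by the
configuration validator.

### VF and PEA

A ventricular-fibrillation episode holds baseline pulsatile flow until
`vf_onset_s`, marks onset with 1.5 s of broadband velocity noise (SD
25 cm/s) — the transient a fibrillating myocardium writes on the Doppler
display — then sets velocity to zero-mean noise and collapses arterial
pressure to a non-pulsatile ~15 mmHg with a 1-s time constant. ECG beat
events stop at onset and resume at ROSC, `defib_delay_s` (default 30 s,
never more than the 60-s untreated-VF cap) after onset. Consecutive
episodes are spaced 300 s onset to onset.

True PEA keeps organized ECG events at the configured heart rate while
systolic pressure sits at 20 mmHg and velocity is near-pulseless around
10 cm/s. "Near-pulseless" is operationalized as ECG-locked amplitude
modulation of at most 20% of the mean — the configuration validator rejects
more — plus additive noise.

### Hierarchical studies

`gen_study()` draws animal intercepts (SD 9.381 cm/s), sequence-within-
animal intercepts (SD 2.449) and optional per-animal random slopes from
zero-mean normals, adds them to the TAV coupling of each generated VCO
sequence, and emits a long-format table at 1 Hz with residual noise (SD
2.449) on each TAV reading. The default intercept SDs put the variance
decomposition at 88 : 6 : 6, i.e. intraclass correlations of 0.88 (animal)
and 0.94 (within animal). Sequence durations are drawn uniformly on
30–69 s and rescaled so the study mean is 50 s. Per-sequence baseline and
nadir pressure levels are drawn around the configured values with the
observed between-sequence SDs, clamped to the observed ranges; the EDV
calibration endpoints are left fixed so the reverse-flow anchor stays
deterministic. Every sequence consumes its own child RNG stream derived
from the root seed, which makes the dataset bit-reproducible and lets the
table-only fast path (`keep_traces = FALSE`) skip waveform rendering without
changing a single table value.

What the generator does **not** emulate: ECG waveform morphology (events
only), respiration and probe-motion artifacts, chest-compression artifacts,
beat-to-beat heart-rate variability, and the full covariance structure of
real Table-style summaries (only the means, and the SDs of the pressure
anchors, are reproduced). Tests passing on this generator therefore
demonstrate correctness of the measurement chain under its stated forward
model, not clinical performance.

## The acquisition forward model

Each transducer sees the flow axis at `phi = alpha ∓ 30°`, where `alpha` is
the vessel inclination. For every gate whose depth intersects the 5-mm
lumen, the slow-time IQ signal is a sum of 50 scatterer phasors. A
scatterer sits at radius `r` in the chord the gate samples and carries the
blunt profile factor `1 − (r/R)^4`, so its instantaneous Doppler frequency
is `f_d(t) = 2 f0 v_s(t) cos(phi) / c` and its phase is the cumulative sum
of `2π f_d / PRF` (computed in C++; the phasor sum is the single hot loop of
the synthesis). The phasor sum — not a single tone — is what produces
physical spectral broadening: the velocity distribution across the lumen
piles up near the centreline value, so the spectral envelope estimates
centreline velocity. Complex white noise enters at −SNR dB relative to the
unit flow power, and clutter (stationary tissue plus slow wall motion) as a
+40 dB near-DC tone with a random-walk phase of ~2 Hz RMS. Gates outside
the lumen carry clutter and noise only. Depth-dependent attenuation, beam
profiles and focusing are not modelled — the physical apertures are
unfocused — so amplitude is uniform across gates.

The PRF default of 15 kHz is a design choice the hardware leaves open: it
respects the range-ambiguity bound at the 45-mm deepest gate
(`c / (2 z_max)` ≈ 17.1 kHz) while keeping the fastest calibrated systolic
velocities (~142 cm/s × cos 30° → 6.4 kHz) under the 7.5-kHz Nyquist limit.
The synthesizer checks the bound per record and either warns or refuses
(configurable) when a scenario would alias.

## The measurement chain

* **Wall filter.** Zero-phase high-pass along slow time with the
  magnitude-squared response of a 4th-order Butterworth at 100 Hz, applied
  in the frequency domain. 100 Hz corresponds to ~1.9 cm/s axial velocity,
  far below the slowest diastolic flows of interest (~8 cm/s axial at
  baseline). DC is removed exactly; a tone at twice the cutoff loses less
  than 0.1 dB.
* **Colour M-mode.** Per gate and 20-ms frame, mean velocity from the phase
  of the lag-1 slow-time autocorrelation (the classic autocorrelation
  estimator) and mean power. Exact for noise-free tones, which the tests
  exploit.
* **Gate selection.** Score = variance of the frame-rate mean-velocity
  series inside the 0.5–4 Hz heart-rate band × mean power; the best gate
  wins, ties break shallower, and a best score below 1 (in unit-power ×
  (cm/s)² units) is declared flow-free. The threshold separates pulsatile
  flow gates (scores in the hundreds) from clutter residue (≪ 1) by orders
  of magnitude on synthetic records.
* **Spectrogram.** 10-ms Hann windows, 75% overlap, 256-point FFT, axis
  mapped to velocity with no angle assumed (axial velocities). One
  frequency bin is ~59 Hz ≈ 1.1 cm/s.
* **Envelope.** Per frame and per direction, the envelope is the smallest
  |v| whose cumulative above-noise in-direction power reaches 95% of that
  direction's total; the composite takes the direction holding more
  above-noise power; 5-frame median smoothing. The noise floor is the
  per-frame median bin power times an 8-dB margin; a frame whose
  above-noise power does not clearly exceed what noise alone leaks past the
  margin (~1% of bins) is flagged low-quality and carries envelope 0 — the
  envelope is defined on every frame, never gapped. The 95th percentile
  slightly undershoots the true maximum velocity (the broadened band has
  finite width); at SNR 20 dB the bias is within a few percent, which the
  end-to-end tests bound.
* **Beat segmentation** runs on the envelope itself, not the ECG, so the
  device is self-contained: prominence-based systolic peak detection
  (default prominence 10 cm/s, refractory 0.25 s), onsets refined from the
  diastolic trough to the point 15% up the systolic upstroke. The refinement
  matters: the diastolic tail is flat, so the raw trough position jitters by
  tens of milliseconds and smears windowed averages, while the upstroke
  crossing is sharp. EDV is read at the trough just before the next
  upstroke (median of ±2 frames), PSV is the in-beat maximum, TAV the
  in-beat mean; RI = (PSV−EDV)/PSV, PI = (PSV−EDV)/TAV (NaN when TAV = 0),
  HR = 60/period.
* **Angle correction** happens only at the metrics stage — the spectrogram
  and envelope stay axial, mirroring how such devices defer correction to
  post-processing. From per-beat TAVs of the two transducers,
  `alpha = atan((TAV1 − TAV2) / ((TAV1 + TAV2) tan 30°))` and
  `v = (TAV1 + TAV2) / (2 cos 30° cos alpha)`; this is the unique two-unknown
  inversion of the cosine projections and round-trips to 1e-9. The
  corrected PSV/EDV columns divide each transducer's value by its estimated
  `cos(phi_k)` and average the two. RI, PI and HR are computed from
  uncorrected velocities; as ratios and timings they cancel the cosine
  factor, which the angle-invariance tests verify to 2%.
* **Flow-state classification** over 2-s windows: `pulsatile` when beats
  are present and windowed PSV ≥ 20 cm/s; otherwise `low_flow_pea` when
  organized ECG events are present (the only consumer of the ECG stream);
  otherwise `no_flow`. The 20 cm/s and 12 cm/s thresholds and the 2-s
  window are operational defaults chosen for the simulator's regimes, not
  literature values, and are exposed as arguments.

## The statistics stage

The study analysis fits
`TAV = β0 + β1 MAP + β2 MAP² + a_animal + b_sequence(animal) + ε`
with `lme4`, MAP centred at its grand mean before polynomial expansion (for
conditioning) and coefficients reported back on the raw scale. Random
slopes of the centred MAP polynomial within animals are available as an
option for prediction curves.

Two estimator decisions deserve emphasis:

* **REML, not ML, is the default.** With seven animals, ML variance
  components are biased low by the fixed-effect degrees of freedom, and the
  ICC — a concave ratio of a noisily estimated variance — inherits a
  further downward Jensen bias that no estimator removes. In simulation at
  the reference design (7 × 6 × 60, true ICCs 0.88/0.94), mean recovered
  animal-level ICC is ≈ 0.82 under ML and ≈ 0.84 under REML. REML is the
  standard small-sample choice and is what `compute_icc()` uses.
* **ICCs always come from an intercepts-only decomposition.** Under random
  slopes the intercept variance decomposition is not constant in MAP, so
  there is no single ICC to report; `compute_icc()` therefore refits an
  intercepts-only REML companion when handed a slopes model, and documents
  the slopes fit separately. `icc_animal = σ²_a / (σ²_a + σ²_s + σ²_e)`,
  `icc_within = (σ²_a + σ²_s) / (σ²_a + σ²_s + σ²_e)`.

Confidence intervals are parametric-bootstrap percentiles (default 200
refits via `simulate()`/`refit()`), since the original estimation software's
interval method is not specified by any output the package consumes. A
refit failure rate above 20% raises a warning flag. Per-animal prediction
curves evaluate fixed effects plus the animal's random effects over that
animal's observed MAP range and refuse extrapolation beyond a 10% margin.

## Numerical and interface choices

* Seeds: every generator takes an optional integer seed and runs in a
  private RNG stream (`withr`), leaving the caller's RNG untouched; studies
  derive per-sequence child streams from the root seed.
* Degenerate inputs: all-noise records give the no-flow gate sentinel and
  an empty beat table rather than errors; zero TAV gives the NaN PI
  sentinel; empty envelope frames are flagged, not dropped.
* Containers: traces and metrics are full-precision CSV (`%.17g`, which
  round-trips IEEE doubles bit-exactly); the dual IQ record is a two-file
  plain container (`.meta.json` + long-format `.iq.csv`) with a format
  version field, checked on read. Configuration is YAML with unknown keys
  rejected; every CLI run writes a manifest with per-file md5 hashes.
* Clock alignment for the 6-s sync channel matches pulses by nearest
  neighbour after a coarse median shift, fits `t_b = offset + (1+drift) t_a`
  by least squares, and repeats once after MAD-based outlier rejection.

## Problem sizes used by the test suite

The shipped tests run the full chain on 12-s occlusions (plus 4-s baseline)
and reserve full-length 60-s default-calibration sequences for the
calibration-recovery test (six sequences through the whole acquisition and
measurement chain); the statistics recovery uses 20 replicates of the
7 × 6 × 60 design through the table-only study path.
These sizes were chosen so the whole suite exercises every stage, including
the C++ synthesis core, at full PRF (15 kHz) and full gate count (32)
without scaling down the signal model itself.

## Known limitations

* The beat template's PSV/TAV/EDV coupling is over-determined (above); PSV
  at deep hypotension runs high.
* The envelope percentile tracer reports the 95% power point, a small
  systematic undershoot of the true maximum velocity; raising the
  percentile trades bias for noise sensitivity.
* Beat detection needs one leading and one trailing systolic peak, so the
  first and last simulated beats of a record are not scored.
* The wall filter imposes a dead zone: diastolic flow slower than a few
  cm/s (axial) sits in the 100-Hz filter's transition band, and the
  envelope reads a broadened remnant of several cm/s instead. During a VCO
  this affects the handful of beats where the end-diastolic velocity
  crosses zero; TAV/EDV recovery claims hold for beats outside the dead
  zone, and the calibrated anchors (baseline EDV +10, nadir EDV −29 cm/s)
  are far from it.
* The angle estimate inherits any systematic envelope difference between
  the transducers (e.g. from their independently selected gates); on
  synthetic records the residual bias is a few degrees at worst, which
  perturbs corrected speeds by well under 1%.
* The flow-state classifier is threshold-based and tuned to the simulator's
  regimes; on real data its thresholds would need calibration against
  recordings with ground truth.
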