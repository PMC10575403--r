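---
title: "Methods: speed-adaptive gait phase estimation from a thigh IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speed-adaptive gait phase estimation from a thigh IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitphase)
```

## The estimation problem

A wearable robot needs to know *where in the gait cycle* its user is, every
millisecond, from body-worn sensing alone. This package estimates that gait
phase from one thigh-mounted 6-axis IMU using the phase-portrait principle:
during walking the sagittal thigh angle θ and its rate θ̇ trace a closed,
clockwise loop, and the polar angle of the (normalized) portrait point is
the phase. The convention throughout is 0 % = maximum hip flexion, phase in
[0, 100) with φ% = 50·φ/π.

The portrait method is attractive because it needs no training data and no
per-user calibration, but two obstacles block a naive online version:

* the kinematic signals must be low-pass filtered (ground-impact bursts,
  mounting misalignment, differentiation noise), and any causal filter lags;
  a *fixed* cutoff makes that lag grow with gait frequency, so the estimated
  phase at a fixed physical event drifts as the wearer speeds up;
* the normalization parameters (portrait center and amplitudes) must be
  re-estimated every stride, and a raw per-stride update makes the portrait
  — and hence the phase — jump discontinuously.

The pipeline addresses both: a gait-frequency-adaptive filter whose lag at
the fundamental is a speed-independent, exactly compensable constant, and an
IIR-smoothed normalization-parameter update.

## Pipeline and assumptions

`process_stream()` executes, strictly causally per sample:

1. **Complementary fusion** (`complementary_filter()`):
   θₖ = λ(θₖ₋₁ + ωₖΔt) + (1−λ)·atan2(a_ant, a_long), λ = τ/(τ+Δt).
   Assumes the accelerometer reads mostly gravity at low frequency (no
   centripetal-acceleration correction) and the gyro's sagittal axis is
   configured correctly (`fusion_config()`).
2. **Adaptive low-pass** (`gfaf_filter()` / inlined): n identical
   backward-Euler first-order stages
   yᵢ[k] = (yᵢ[k−1] + ω_c·Ts·x[k])/(1 + ω_c·Ts), with ω_c = α·ω̂_gait
   re-read every sample. This is deliberately an n-fold product of identical
   first-order sections — *not* a maximally-flat Butterworth polynomial —
   because the closed-form lag algebra (lag at the fundamental =
   n·atan(1/α), independent of ω_gait) holds exactly for that form.
3. **Differentiation**: backward difference of the *filtered* angle. The
   pipeline filters first and differentiates second; differentiating the
   raw fused angle first would amplify noise precisely where the portrait
   needs smoothness, and with a linear filter the two orders are
   algebraically equivalent anyway.
4. **Stride segmentation** (`detect_max_flexion()`): an event fires when θ̇
   crosses + → − while θ exceeds its smoothed center, with a refractory
   window of 0.4·T_stride. Maximum flexion is used because it is the
   impact-free point of the cycle. The elapsed interval (clamped to
   [0.4, 2.5] s, the physiologic cadence band) becomes T_stride, and the
   stride's min/max of θ and θ̇ become the held normalization targets
   (centers = midpoints, amplitudes = half-ranges).
5. **Parameter smoothing** (`smooth_param_step()`): every sample,
   y[k] = a·y[k−1] + (1−a)·target, a = 0.98. At 1 kHz this is a ~50 ms time
   constant: fast enough to settle well within a stride, slow enough that a
   parameter update never kinks the portrait. The estimated gait frequency
   is smoothed with the same pole and drives the cutoff *continuously* —
   updating ω_c only at stride events would re-introduce exactly the kind of
   discontinuity the smoother exists to remove.
6. **Phase, compensation, percent**: φ = atan2(−θ̇ₙ, θₙ) mod 2π (identical
   to the three-branch clockwise-angle definition, but well-defined at
   θₙ = 0), then φ_comp = (φ + n·atan(1/α)) mod 2π, then percent. Both the
   uncompensated and compensated phases are emitted (`phi_rad`,
   `phi_comp_rad`): the 0 %-at-max-flexion anchor refers to the
   uncompensated portrait, and compensation shifts the reported phase
   forward by the constant lag.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `tau` | 1.0 | s | complementary crossover (~0.16 Hz); gravity below, gyro above. Chosen, not prescribed: the filter is named in the source method, its gains are not. |
| `n` | 2 | – | filter order. Never printed by the source method, but its printed lag 0.761 rad = 2·atan(1/2.5) pins n = 2; kept configurable. |
| `alpha` | 2.5 | – | cutoff/gait-frequency ratio; lag = n·atan(1/α). Larger α → less lag, less smoothing. |
| `pole` (a) | 0.98 | – | normalization smoother pole; 0 disables (negative control reproduces the discontinuous behaviour). |
| `T0` | 1.1 | s | bootstrap stride period before two events have been seen. |
| `prior_A_theta` | 0.35 | rad | bootstrap amplitude prior; velocity amplitude prior 2π·A/T0. |
| `refractory` | 0.4 | ·T_stride | suppresses double events from secondary waveform humps. |
| `T_clamp` | [0.4, 2.5] | s | cadence band; survives degenerate stride periods. |
| `cutoff_clamp` | [0.5, 50] | rad/s | keeps the adaptive cutoff physical. |
| `cutoff_hz` | 1.5 | Hz | fixed cutoff of the LPF baseline. |

Startup is undefined in the source method; here, output is flagged
`converged = FALSE` until two full strides have completed, and downstream
statistics additionally drop the first three strides of each trial.

## The synthetic world

`synth_trial()` generates what the estimator is later measured on, so its
assumptions matter:

* **Trajectory**: θ(t) = offset + A₁cos(ψ+p₁) + A₂cos(2ψ+p₂), with ψ̇ =
  2π·f_stride(speed). Two harmonics reflect the two dominant peaks seen in
  spectral analyses of real thigh angles; defaults A₁ = 0.35 rad,
  A₂ = 0.08 rad (at 1 m/s, +20 %/(m/s)), phases (0, π) put maximum flexion
  exactly at ψ = 0 and a deeper, sharper extension trough — a gait-like
  asymmetry. Real per-subject amplitudes are not published in the source
  material; these are explicit stand-ins.
* **Speed dependence**: f_stride rises linearly, 0.75 Hz at 0.6 m/s to
  1.05 Hz at 1.6 m/s (typical adult treadmill values; the source only
  establishes that frequency rises with speed).
* **Variability**: instantaneous stride frequency wanders multiplicatively
  (one-pole-filtered white noise, ~0.5 Hz bandwidth, 3 % relative SD).
  Without it, TBE would be an unrealistically perfect estimator.
* **Sensors**: gyro = θ̇ + N(0, 0.02 rad/s); accel = gravity decomposed by θ
  + N(0, 0.15 m/s²) + a 30 m/s², 60 Hz, 20 ms-decay burst at each heel
  strike (accelerometer only). All noise derives from one seed through
  independent per-channel sub-streams; generation is bit-reproducible.
* **Ground truth**: phase is ψ itself (re-anchored at the flexion maximum),
  exact by construction; heel strike and toe-off sit at fixed cycle
  fractions (17.24 % / 55.14 %); the vGRF stream is built so the
  10 %-of-body-weight threshold is crossed exactly at those instants.

What it does **not** emulate: stride-to-stride waveform shape changes,
pathological gaits, sensor bias/drift and scale error, soft-tissue artifact,
centripetal acceleration, non-sagittal motion, and any stance/swing
asymmetry beyond the second harmonic. A green test therefore establishes
algorithmic correctness under a plausible periodic-kinematics world — not
clinical performance.

## Interpreting phase: linearity vs repeatability

For a **pure sinusoid** the portrait phase equals the true linear phase, and
the noise-free round trip through the full pipeline recovers ground truth to
well under 1 % of cycle after convergence (tested). With **harmonic
content** the portrait phase is a *monotone reparameterization* of the
cycle, not the linear phase: with the default 0.08 rad second harmonic the
two differ by several percent at mid-cycle, and events anchor at a
shape-dependent offset (heel strike lands near 12.7 % portrait phase rather
than its 17.24 % time fraction). This is a property of the portrait method
itself, not an implementation artifact, and it is harmless for phase-based
control, which needs the *same* phase at the *same* event every stride. The
tests mirror this split: sample-wise truth recovery is asserted in the
sinusoid world; monotonicity, continuity, and event-phase repeatability in
the full default world.

Similarly, the normalization parameters track the extrema of the *filtered*
signal: at α = 2.5 the cascade attenuates the fundamental by
1/(1+1/α²) = 0.862, so tracked amplitudes are correspondingly smaller than
the raw-signal truth — by design, since the portrait is built from the
filtered signal. Parameter recovery against generator truth is therefore
tested at α = 25 (gain 0.997), where the filter is essentially transparent;
at the default α the phase stays exact because both portrait axes shrink
together.

## Numerical choices

* Backward-Euler discretization everywhere (filter stages, differentiation,
  smoothers): strictly causal, unconditionally stable, matches an
  embedded-implementation style. The discrete cascade's lag differs from
  the continuous closed form by under 0.001 rad at 1 kHz over the gait band
  (measured by a cross-spectral oracle in the tests).
* Filter state initialized to the first fused angle, so filtering starts
  without a step transient; `gfaf_filter()`'s standalone default initializes
  at 0 (a quiescent filter).
* Time-varying ω_c is applied with state carried over — cutoff changes are
  bumpless.
* Degenerate strides (amplitude ≤ 1e−6, e.g. standing) raise a typed
  condition internally and leave the previous parameters in place; an
  all-zero stream yields `NA` phase with `converged = FALSE` rather than an
  error, since a streaming estimator must survive non-walking input.
* Event timing uses linear interpolation for GRF threshold crossings and
  nearest-sample lookup for phase-at-event; phase statistics are circular
  (deviations unwrapped about the circular mean in (−50, 50]), with the
  sample (n−1) SD. The source events sit far from the 0/100 wrap, but the
  LPF baseline's drifted heel-strike phase does wrap — pooled statistics
  would be garbage without circular handling.
* Cross-spectral lag measurement projects onto the exact fundamental bin
  over a whole number of periods (leakage-free), rather than Welch phase
  averaging; `dominant_frequency()` uses 4-segment, 50 %-overlap Hann Welch
  averaging with a peak-to-median ratio ≥ 5 confidence gate.
* TBE saturates at 100 − ε instead of wrapping when a stride runs long: a
  time-based estimator cannot anticipate the next event, and emitting a
  phantom wrap would fabricate a stride.

## Known limitations

* Sagittal-plane only; one module instance per leg; no bilateral fusion.
* No quaternion/Kalman orientation estimation; heavy non-sagittal motion
  (circumduction) breaks the single-axis assumption.
* The complementary filter ignores centripetal acceleration; at high
  cadence this biases the accelerometer inclination slightly (the GFAF
  absorbs most of it, but it is unmodeled).
* Bootstrap behaviour (first two strides) uses priors and is explicitly
  flagged unconverged; control should gate on the `converged` column.
* The pooled event-phase statistics treat all speeds as one population;
  per-speed tables are available in `compare_report()$per_trial`.
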