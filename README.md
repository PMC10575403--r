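# gaitphase

Speed-adaptive online estimation of the **gait phase** — the position within
the gait cycle, expressed in [0, 100) % and anchored at **maximum hip
flexion** — from a single thigh-worn 6-axis IMU. The target users are
developers of gait-assistive robots (exoskeletons, exosuits, prostheses) who
need a phase signal that stays continuous, monotone, and repeatable while
the wearer speeds up and slows down.

## The method

The thigh angle θ (sagittal plane, flexion positive) and its derivative θ̇
trace a clockwise loop in the (θ, θ̇) plane. After shifting the loop to the
origin and scaling both axes to unit amplitude,

  θₙ = (θ − θₒ)/A_θ,  θ̇ₙ = (θ̇ − θ̇ₒ)/A_θ̇,

the phase is the clockwise portrait angle φ = atan2(−θ̇ₙ, θₙ) mod 2π, and
φ% = 50·φ/π. Three ingredients make this work online across speeds:

1. **Sensor fusion.** A complementary filter blends accelerometer
   inclination (reliable at low frequency) with integrated gyroscope rate
   (reliable at high frequency): θₖ = λ(θₖ₋₁ + ω·Δt) + (1−λ)·θ_accel, with
   λ = τ/(τ+Δt).
2. **Gait-frequency-adaptive filter (GFAF).** Ground impact and sensor
   misalignment demand low-pass filtering, but a fixed-cutoff filter's lag
   −n·atan(ω/ω_c) grows with gait frequency, distorting phase at higher
   speeds. The GFAF ties its cutoff to the current gait frequency,
   ω_c = α·ω_gait with ω_gait = 2π/T_stride, so the lag at the fundamental
   collapses to the **speed-independent constant n·atan(1/α)**
   (0.761 rad for n = 2, α = 2.5) which is simply added back:
   φ_comp = (φ + n·atan(1/α)) mod 2π.
3. **Smoothed online normalization.** θₒ, θ̇ₒ, A_θ, A_θ̇ are re-estimated
   from the min/max of the previous stride at each maximum-flexion event
   (where the signal is impact-free), and passed through the first-order IIR
   smoother H(z) = (1−a)/(1−a·z⁻¹) with pole a = 0.98 at the sample rate, so
   the per-stride update never produces a phase discontinuity.

The package also implements the two conventional baselines used for
comparison — the phase portrait with a fixed 1.5 Hz low-pass filter (LPF)
and time-based estimation (TBE, elapsed time over previous stride period) —
plus ground-truth event detection from vertical GRF (10 %-of-body-weight
threshold), evaluation metrics, and a synthetic multi-speed gait generator
with exact ground-truth phase.

## Worked example

Six constant-speed synthetic trials spanning 0.6–1.6 m/s (25 s each, 500 Hz,
3 % stride-frequency jitter, heel-strike impact bursts, sensor noise), all
three estimators, phase sampled at the ground-truth heel-strike and toe-off
times:

```r
library(gaitphase)
trials <- make_trial_set(speeds = seq(0.6, 1.6, by = 0.2), duration = 25,
                         fs = 500, seed = 42)
rep <- compare_report(trials, config = phase_config(fs = 500))
print(rep$stats, digits = 3)
#>   method       event mean_phase std_phase n_strides
#> 1   gfaf heel_strike       12.7     0.157       113
#> 2   gfaf     toe_off       53.7     0.683       111
#> 3    lpf heel_strike       97.2     1.243       107
#> 4    lpf     toe_off       36.5     1.616       111
#> 5    tbe heel_strike       19.2     1.347       113
#> 6    tbe     toe_off       57.1     2.121       111
print(rep$reduction, digits = 3)
#>   baseline       event reduction_pct
#> 1      lpf heel_strike          87.4
#> 2      lpf     toe_off          57.7
#> 3      tbe heel_strike          88.3
#> 4      tbe     toe_off          67.8
```

Reading the table: `std_phase` is the repeatability metric — the sample SD
(circular-safe) of the estimated phase at the same physical event, pooled
over all speeds. The adaptive method reports heel strike at 12.7 ± 0.16 % of
the cycle regardless of speed; the fixed low-pass baseline both drifts with
speed (hence the inflated SD) and sits at a wrong, speed-dependent phase
(97.2 % ≈ −2.8 %, its uncompensated lag having pushed heel strike past the
wrap); TBE suffers from stride-period variability. `reduction_pct` is
100·(SD_baseline − SD_gfaf)/SD_baseline.

The command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/gaitphase simulate --speed 1.0 --duration 30 --seed 1 --out data/
Rscript inst/cli/gaitphase run --input data/trial_imu.csv --method gfaf \
    --alpha 2.5 --order 2 --pole 0.98 --fs 1000 --out phase.csv
Rscript inst/cli/gaitphase compare --seed 1 --out report.csv
```

## Further reading

See the methods vignette (`vignettes/methods.Rmd`) for the model
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, and known limitations.
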