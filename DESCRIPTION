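Package: gaitphase
Title: Speed-Adaptive Online Gait Phase Estimation from Thigh IMU Data
Version: 0.1.0
Authors@R:
    person("GPEM", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Streaming estimation of the gait phase (percent of the gait
    cycle, anchored at maximum hip flexion) from a thigh-worn inertial
    measurement unit. Implements complementary-filter sensor fusion of
    accelerometer and gyroscope data, a gait-frequency-adaptive low-pass
    filter whose phase lag at the gait frequency is constant across walking
    speeds and therefore compensable by a closed-form constant, online
    phase-portrait normalization with per-stride parameter updates smoothed
    by a first-order IIR filter, and phase computation on the normalized
    portrait. Ships two conventional baselines (fixed-cutoff low-pass
    portrait and time-based estimation), ground-truth event detection from
    vertical ground reaction force, evaluation metrics, and a synthetic
    multi-speed gait generator so the whole pipeline is testable without
    human-subject recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
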