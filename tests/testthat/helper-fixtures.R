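# Shared fixtures, all generated in code. Heavy objects are memoized so the
# multi-speed trial set and its method-comparison report are computed once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

# noise-free, jitter-free, impact-free pure-sinusoid gait: the configuration
# in which the estimator is exact up to the compensation residual
quiet_params <- function(seed = 3L, A = 0.35) {
  gait_model_params(harmonic_amplitudes = c(A, 0), freq_jitter_std = 0,
                    noise_std_gyro = 0, noise_std_accel = 0,
                    impact_amplitude = 0, seed = seed)
}

# circular difference of two percent phases, in (-50, 50]
pct_diff <- function(a, b) (a - b + 50) %% 100 - 50

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, fn(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# seeded multi-speed trial set (default generator world) + comparison report
compare_fixture <- function() {
  memo("compare", function() {
    trials <- make_trial_set(speeds = seq(0.6, 1.6, by = 0.2), duration = 25,
                             fs = 500, seed = 42L)
    cfg <- phase_config(fs = 500)
    list(trials = trials, config = cfg,
         report = compare_report(trials, config = cfg))
  })
}

# one default-world constant-speed trial
default_trial <- function() {
  memo("default_trial", function() {
    synth_trial(1.0, duration = 15, params = gait_model_params(seed = 9),
                fs = 500)
  })
}
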