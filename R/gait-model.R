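#' Parameters of the synthetic thigh-kinematics model
#'
#' The synthetic generator models the sagittal thigh flexion angle as a
#' two-harmonic oscillation driven by an accumulated gait angle psi(t):
#' theta(t) = offset + A1*cos(psi + p1) + A2*cos(2*psi + p2), where
#' d(psi)/dt = 2*pi * f_stride(speed(t)) * jitter(t). Two harmonics reproduce
#' the two dominant spectral peaks of real thigh-angle recordings while
#' keeping the ground-truth phase (psi itself, re-anchored at maximum
#' flexion) exact by construction.
#'
#' Amplitudes scale by +20 % per m/s around 1.0 m/s, and stride frequency
#' rises linearly with speed (0.75 Hz at 0.6 m/s to 1.05 Hz at 1.6 m/s,
#' typical adult treadmill values). Stride-to-stride variability is emulated
#' by a slow multiplicative wander of the instantaneous stride frequency
#' (one-pole-filtered Gaussian noise, default 3 % relative SD). Heel-strike
#' ground impact is an exponentially decaying high-frequency burst added to
#' the accelerometer channels only.
#'
#' @param angle_offset Mean thigh angle, rad.
#' @param harmonic_amplitudes Length-2 positive vector, rad: fundamental and
#'   second-harmonic amplitude at 1.0 m/s.
#' @param harmonic_phases Length-2 vector, rad: phase offsets of the two
#'   harmonics. The defaults place maximum flexion exactly at psi = 0.
#' @param amp_speed_slope Fractional amplitude change per m/s of speed.
#' @param stride_freq_fn Function mapping speed (m/s) to stride frequency
#'   (Hz); must be monotone increasing.
#' @param hs_fraction,to_fraction Heel-strike and toe-off location as percent
#'   of the gait cycle (0 % = maximum flexion).
#' @param freq_jitter_std Relative SD of the stride-frequency wander
#'   (0 disables it).
#' @param noise_std_gyro Gyroscope white-noise SD, rad/s.
#' @param noise_std_accel Accelerometer white-noise SD, m/s^2.
#' @param impact_amplitude Peak amplitude of the heel-strike burst, m/s^2.
#' @param impact_decay Exponential decay time of the burst, s.
#' @param impact_freq Carrier frequency of the burst, Hz.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A list of class `gait_model_params`.
#' @export
gait_model_params <- function(angle_offset = 0.05,
                              harmonic_amplitudes = c(0.35, 0.08),
                              harmonic_phases = c(0, pi),
                              amp_speed_slope = 0.2,
                              stride_freq_fn = default_stride_freq,
                              hs_fraction = 17.24,
                              to_fraction = 55.14,
                              freq_jitter_std = 0.03,
                              noise_std_gyro = 0.02,
                              noise_std_accel = 0.15,
                              impact_amplitude = 30,
                              impact_decay = 0.02,
                              impact_freq = 60,
                              seed = 1L) {
  stopifnot(length(harmonic_amplitudes) == 2, all(harmonic_amplitudes >= 0),
            harmonic_amplitudes[1] > 0,
            length(harmonic_phases) == 2,
            hs_fraction > 0, hs_fraction < to_fraction, to_fraction < 100,
            freq_jitter_std >= 0, noise_std_gyro >= 0, noise_std_accel >= 0,
            impact_amplitude >= 0, impact_decay > 0, impact_freq > 0,
            is.function(stride_freq_fn))
  # monotonicity spot-check of the speed -> frequency map
  v <- seq(0.4, 2.0, by = 0.2)
  fv <- vapply(v, stride_freq_fn, numeric(1))
  if (any(diff(fv) <= 0))
    stop("stride_freq_fn must be monotone increasing in speed")
  structure(list(angle_offset = angle_offset,
                 harmonic_amplitudes = harmonic_amplitudes,
                 harmonic_phases = harmonic_phases,
                 amp_speed_slope = amp_speed_slope,
                 stride_freq_fn = stride_freq_fn,
                 hs_fraction = hs_fraction,
                 to_fraction = to_fraction,
                 freq_jitter_std = freq_jitter_std,
                 noise_std_gyro = noise_std_gyro,
                 noise_std_accel = noise_std_accel,
                 impact_amplitude = impact_amplitude,
                 impact_decay = impact_decay,
                 impact_freq = impact_freq,
                 seed = as.integer(seed)),
            class = "gait_model_params")
}

#' Default linear speed-to-stride-frequency map
#'
#' 0.75 Hz at 0.6 m/s rising to 1.05 Hz at 1.6 m/s (0.3 Hz per m/s).
#' @param speed Walking speed, m/s.
#' @return Stride frequency, Hz.
#' @export
default_stride_freq <- function(speed) 0.75 + 0.3 * (speed - 0.6)

# psi value of the global maximum of the two-harmonic waveform over one cycle.
# With the default phases (0, pi) and A2 < A1/4 this is exactly 0; computed
# numerically so non-default shapes stay correct.
psi_at_max_flexion <- function(params) {
  f <- function(psi) {
    params$harmonic_amplitudes[1] * cos(psi + params$harmonic_phases[1]) +
      params$harmonic_amplitudes[2] * cos(2 * psi + params$harmonic_phases[2])
  }
  grid <- seq(0, 2 * pi, length.out = 4096L)
  p0 <- grid[which.max(f(grid))]
  opt <- stats::optimize(f, lower = p0 - 0.01, upper = p0 + 0.01,
                         maximum = TRUE, tol = 1e-10)
  ps <- opt$maximum %% (2 * pi)
  # snap optimizer dust at the wrap so a peak at exactly 0 stays 0
  if (min(ps, 2 * pi - ps) < 1e-6) ps <- 0
  ps
}

# Slow multiplicative wander of stride frequency: white Gaussian noise through
# a one-pole low-pass (~0.5 Hz), rescaled to the requested relative SD.
frequency_jitter <- function(n, fs, rel_sd, seed) {
  if (rel_sd <= 0 || n < 2) return(rep(1, n))
  set.seed(seed)
  w <- stats::rnorm(n)
  a <- exp(-2 * pi * 0.5 / fs)           # pole for ~0.5 Hz bandwidth
  z <- as.numeric(stats::filter(w * (1 - a), a, method = "recursive"))
  z <- z / stats::sd(z)
  pmax(1 + rel_sd * z, 0.2)              # guard against non-physical freezing
}

#' Generate ground-truth thigh kinematics for a speed profile
#'
#' Integrates the gait angle psi(t) over the profile, evaluates the
#' two-harmonic thigh trajectory, and derives exact ground-truth phase and
#' event times. The ground-truth phase is `(psi - psi_max_flexion) mod 2*pi`
#' expressed in percent, so 0 % always coincides with maximum hip flexion.
#' Heel-strike and toe-off times are placed at fixed fractions of each cycle.
#'
#' @param profile A [make_speed_profile()] object.
#' @param params A [gait_model_params()] object.
#' @param fs Sampling frequency, Hz (>= 100).
#' @param duration Optional trial length in s; defaults to the profile span.
#' @return A list with `truth` (data.frame `t, theta, theta_dot, phase_pct`),
#'   `hs_times`, `to_times`, `max_flexion_times` (s), `stride_freq` (Hz per
#'   sample, jitter included), and the inputs.
#' @export
thigh_trajectory <- function(profile, params = gait_model_params(), fs = 1000,
                             duration = NULL) {
  stopifnot(inherits(profile, "speed_profile"),
            inherits(params, "gait_model_params"), fs >= 100)
  if (is.null(duration)) duration <- profile_duration(profile)
  stopifnot(duration > 0)
  n <- floor(duration * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  v <- speed_at(profile, t)
  if (any(!is.finite(v))) stop("non-finite speed in profile")
  f0 <- vapply(v, params$stride_freq_fn, numeric(1))
  jit <- frequency_jitter(n, fs, params$freq_jitter_std,
                          seed = params$seed + 104729L)
  f <- f0 * jit
  # accumulated gait angle; trapezoidal integration of 2*pi*f
  dpsi <- 2 * pi * (f[-n] + f[-1]) / (2 * fs)
  psi <- c(0, cumsum(dpsi))

  amp_scale <- pmax(1 + params$amp_speed_slope * (v - 1.0), 0.1)
  A1 <- params$harmonic_amplitudes[1] * amp_scale
  A2 <- params$harmonic_amplitudes[2] * amp_scale
  p1 <- params$harmonic_phases[1]
  p2 <- params$harmonic_phases[2]
  theta <- params$angle_offset + A1 * cos(psi + p1) + A2 * cos(2 * psi + p2)
  omega <- 2 * pi * f
  # amplitude drift during ramps is orders of magnitude slower than the
  # oscillation; its contribution to theta_dot is neglected
  theta_dot <- -A1 * omega * sin(psi + p1) - 2 * A2 * omega * sin(2 * psi + p2)

  psi_star <- psi_at_max_flexion(params)
  phase_pct <- ((psi - psi_star) %% (2 * pi)) * 50 / pi

  # event times: invert the monotone psi(t) at target psi values
  k_max <- floor((psi[n] - psi_star) / (2 * pi))
  event_times <- function(frac) {
    targets <- psi_star + 2 * pi * (0:k_max) + 2 * pi * frac / 100
    targets <- targets[targets >= psi[1] & targets <= psi[n]]
    if (!length(targets)) return(numeric(0))
    stats::approx(psi, t, xout = targets)$y
  }
  list(truth = data.frame(t = t, theta = theta, theta_dot = theta_dot,
                          phase_pct = phase_pct),
       hs_times = event_times(params$hs_fraction),
       to_times = event_times(params$to_fraction),
       max_flexion_times = event_times(0),
       stride_freq = f,
       psi = psi, psi_star = psi_star,
       fs = fs, profile = profile, params = params)
}
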