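#' Synthesize 6-axis IMU samples from a thigh trajectory
#'
#' Emulates a thigh-mounted IMU in its body frame: x anterior, y lateral
#' (sagittal rotation axis), z longitudinal along the thigh. The
#' accelerometer reads the gravity vector decomposed by the thigh angle
#' (`ax = g*sin(theta)`, `az = g*cos(theta)`) plus white noise plus an
#' exponentially decaying high-frequency burst starting at each heel strike
#' (ground-impact disturbance). The sagittal gyroscope channel `gy` reads
#' `theta_dot` plus white noise; off-axis channels carry noise only. All
#' randomness derives from `params$seed` via independent per-channel
#' sub-streams, so generation is bit-reproducible.
#'
#' @param traj Output of [thigh_trajectory()].
#' @param params A [gait_model_params()] object (defaults to the one inside
#'   `traj`).
#' @param gravity Gravitational acceleration, m/s^2.
#' @return data.frame `t, ax, ay, az, gx, gy, gz` (s, m/s^2, rad/s).
#' @export
synth_imu <- function(traj, params = traj$params, gravity = 9.80665) {
  stopifnot(inherits(params, "gait_model_params"))
  truth <- traj$truth
  n <- nrow(truth)
  t <- truth$t
  fs <- traj$fs

  # independent sub-streams per channel, all derived from the one seed
  set.seed(params$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 6L)
  chan_noise <- function(i, sd) {
    if (sd <= 0) return(numeric(n))
    set.seed(sub[i]); stats::rnorm(n, sd = sd)
  }

  ax <- gravity * sin(truth$theta) + chan_noise(1L, params$noise_std_accel)
  ay <- chan_noise(2L, params$noise_std_accel)
  az <- gravity * cos(truth$theta) + chan_noise(3L, params$noise_std_accel)
  gx <- chan_noise(4L, params$noise_std_gyro)
  gy <- truth$theta_dot + chan_noise(5L, params$noise_std_gyro)
  gz <- chan_noise(6L, params$noise_std_gyro)

  if (params$impact_amplitude > 0 && length(traj$hs_times)) {
    burst <- impact_burst(t, traj$hs_times, params$impact_amplitude,
                          params$impact_decay, params$impact_freq)
    ax <- ax + burst
    az <- az + 0.5 * burst   # impact couples into both sagittal accel axes
  }
  data.frame(t = t, ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz)
}

# Sum of decaying sinusoidal bursts, one per heel strike. Each burst is
# truncated at 8 decay constants where it is < 0.04 % of its peak.
impact_burst <- function(t, hs_times, amplitude, decay, freq) {
  out <- numeric(length(t))
  dt <- t[2] - t[1]
  horizon <- 8 * decay
  for (ths in hs_times) {
    i0 <- max(1L, ceiling(ths / dt) + 1L)
    i1 <- min(length(t), floor((ths + horizon) / dt) + 1L)
    if (i1 < i0) next
    tl <- t[i0:i1] - ths
    out[i0:i1] <- out[i0:i1] +
      amplitude * exp(-tl / decay) * sin(2 * pi * freq * tl)
  }
  out
}

#' Synthesize a vertical ground-reaction-force stream
#'
#' Produces a smooth single-hump stance load per heel-strike/toe-off pair:
#' the force ramps from zero to 10 % of body weight in a short lead interval
#' ending exactly at the heel strike, follows a half-sine hump peaking at
#' ~1.15 body weight during stance, returns to 10 % of body weight exactly at
#' toe-off, decays to zero just after, and is zero throughout swing. The
#' 10 %-of-body-weight threshold is therefore crossed upward exactly at each
#' heel strike and downward exactly at each toe-off.
#'
#' @param hs_times,to_times Event times in s; each toe-off must follow its
#'   heel strike and stance intervals must not overlap.
#' @param body_weight Body weight in N.
#' @param fs Sampling frequency, Hz.
#' @param duration Stream length in s.
#' @param lead Ramp-in/ramp-out duration in s.
#' @return data.frame `t, vgrf` (s, N).
#' @export
synth_grf <- function(hs_times, to_times, body_weight = 700, fs = 1000,
                      duration, lead = 0.03) {
  stopifnot(body_weight > 0, fs > 0, duration > 0, lead > 0)
  n <- floor(duration * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  vgrf <- numeric(n)
  if (!length(hs_times)) return(data.frame(t = t, vgrf = vgrf))

  # pair each heel strike with the first toe-off after it
  pairs <- lapply(hs_times, function(h) {
    tos <- to_times[to_times > h]
    if (!length(tos)) return(NULL)
    c(h, tos[1])
  })
  pairs <- Filter(Negate(is.null), pairs)
  if (length(pairs) > 1) {
    for (i in seq_len(length(pairs) - 1)) {
      if (pairs[[i]][2] + lead > pairs[[i + 1]][1] - lead)
        stop("overlapping stance intervals in GRF synthesis")
    }
  }
  thr <- 0.1   # threshold as fraction of BW
  peak <- 1.15
  for (p in pairs) {
    hs <- p[1]; to <- p[2]
    # ramp in: 0 at hs - lead, thr*BW at hs
    idx <- which(t >= hs - lead & t < hs)
    vgrf[idx] <- body_weight * thr * (t[idx] - (hs - lead)) / lead
    # stance hump: thr + (peak - thr) * sin(pi * u)
    idx <- which(t >= hs & t <= to)
    u <- (t[idx] - hs) / (to - hs)
    vgrf[idx] <- body_weight * (thr + (peak - thr) * sin(pi * u))
    # ramp out: thr*BW at to, 0 at to + lead
    idx <- which(t > to & t <= to + lead)
    vgrf[idx] <- body_weight * thr * (1 - (t[idx] - to) / lead)
  }
  data.frame(t = t, vgrf = vgrf)
}

#' Generate a complete synthetic walking trial
#'
#' Convenience wrapper chaining [thigh_trajectory()], [synth_imu()] and
#' [synth_grf()] into one `synthetic_trial` object carrying the IMU stream,
#' ground-truth kinematics and phase, event times, and the vGRF stream.
#'
#' @param profile A [make_speed_profile()] object, or a single speed in m/s
#'   (converted to a constant profile of length `duration`).
#' @param params A [gait_model_params()] object.
#' @param fs Sampling frequency, Hz.
#' @param duration Trial length in s (required when `profile` is a speed).
#' @param body_weight Body weight in N for the vGRF stream.
#' @return A list of class `synthetic_trial` with elements `imu`, `truth`,
#'   `vgrf`, `hs_times`, `to_times`, `max_flexion_times`, `stride_freq`,
#'   `body_weight`, `fs`, `params`, `profile`.
#' @examples
#' tr <- synth_trial(1.0, duration = 10, params = gait_model_params(seed = 7))
#' head(tr$imu)
#' @export
synth_trial <- function(profile, params = gait_model_params(), fs = 1000,
                        duration = NULL, body_weight = 700) {
  if (is.numeric(profile) && length(profile) == 1) {
    if (is.null(duration)) stop("duration required for a constant-speed trial")
    profile <- make_speed_profile("constant", speed = profile,
                                  duration = duration)
  }
  traj <- thigh_trajectory(profile, params, fs, duration)
  imu <- synth_imu(traj, params)
  grf <- synth_grf(traj$hs_times, traj$to_times, body_weight, fs,
                   duration = max(traj$truth$t))
  structure(list(imu = imu, truth = traj$truth, vgrf = grf,
                 hs_times = traj$hs_times, to_times = traj$to_times,
                 max_flexion_times = traj$max_flexion_times,
                 stride_freq = traj$stride_freq,
                 body_weight = body_weight, fs = fs,
                 params = params, profile = traj$profile),
            class = "synthetic_trial")
}

#' Write / read trial CSV files
#'
#' The IMU dialect is `t, ax, ay, az, gx, gy, gz`; GRF is `t, vgrf`; truth is
#' `t, theta_true, phase_true_pct`.
#'
#' @param trial A [synth_trial()] object.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_trial_csv <- function(trial, dir, prefix = "trial") {
  stopifnot(inherits(trial, "synthetic_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_imu.csv", "_grf.csv", "_truth.csv")))
  data.table::fwrite(trial$imu, paths[1])
  data.table::fwrite(trial$vgrf, paths[2])
  truth <- data.frame(t = trial$truth$t, theta_true = trial$truth$theta,
                      phase_true_pct = trial$truth$phase_pct)
  data.table::fwrite(truth, paths[3])
  invisible(paths)
}

#' @rdname write_trial_csv
#' @param path Path to an IMU CSV file.
#' @export
read_imu_csv <- function(path) {
  imu <- as.data.frame(data.table::fread(path))
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(imu)))
    stop("IMU CSV must have columns: ", paste(need, collapse = ", "))
  if (any(diff(imu$t) <= 0)) stop("IMU timestamps must be strictly increasing")
  imu[need]
}
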