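#' Fixed-cutoff low-pass portrait baseline
#'
#' The conventional phase-portrait pipeline: identical to [process_stream()]
#' except that the angle is filtered with a fixed-cutoff low-pass cascade
#' (default 1.5 Hz) instead of the gait-frequency-adaptive filter, and no
#' lag compensation is applied - the lag `n*atan(omega/omega_c)` varies with
#' gait frequency, so no constant could compensate it. This is the baseline
#' whose event phase drifts downward as walking speed rises.
#'
#' @param imu IMU data.frame (see [read_imu_csv()]).
#' @param cutoff_hz Fixed cutoff, Hz.
#' @param n Filter order; matches the GFAF order for a fair comparison.
#' @param config A [phase_config()]; its `cutoff_hz` and `n` are overridden
#'   by the arguments.
#' @return Phase stream data.frame, same contract as [process_stream()].
#' @export
lpf_portrait_pipeline <- function(imu, cutoff_hz = 1.5, n = 2,
                                  config = phase_config()) {
  config$cutoff_hz <- cutoff_hz
  config$n <- as.integer(n)
  process_stream(imu, config, method = "lpf")
}

#' Time-based estimation (TBE) baseline
#'
#' Gait phase as elapsed time since the last maximum-flexion event divided by
#' the previous stride period: `phi_pct = min(100*(t - t_event)/T_prev,
#' 100 - eps)`. Events are detected on the raw (unfiltered)
#' complementary-filter angle. The estimate saturates just below 100 %
#' rather than wrapping, because a time-based estimator cannot anticipate
#' the next event when the current stride runs long. Output is NA-flagged
#' until the first stride completes.
#'
#' @param imu IMU data.frame (see [read_imu_csv()]).
#' @param config A [phase_config()].
#' @return Phase stream data.frame, same contract as [process_stream()].
#' @export
tbe_phase <- function(imu, config = phase_config()) {
  process_stream(imu, config, method = "tbe")
}
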