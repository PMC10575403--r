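#' Sensor-fusion configuration
#'
#' The thigh angle is fused from the accelerometer's low-frequency gravity
#' direction and the gyroscope's high-frequency angular rate with a
#' complementary filter. `tau` sets the crossover: gravity dominates below
#' ~1/(2*pi*tau) Hz, the gyroscope above. Axis mapping is configuration
#' because module mounting orientation varies; defaults match the synthetic
#' IMU frame (x anterior, y sagittal rotation axis, z longitudinal).
#'
#' @param tau Complementary time constant, s.
#' @param fs Nominal sampling frequency, Hz (used only when timestamps are
#'   absent).
#' @param gyro_axis Name of the sagittal gyro channel.
#' @param gyro_sign +1/-1 so that flexion rate is positive.
#' @param accel_anterior,accel_longitudinal Accelerometer channel names.
#' @param anterior_sign,longitudinal_sign Channel signs.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(tau = 1.0, fs = 1000,
                          gyro_axis = "gy", gyro_sign = 1,
                          accel_anterior = "ax", anterior_sign = 1,
                          accel_longitudinal = "az", longitudinal_sign = 1) {
  stopifnot(tau > 0, fs > 0, abs(gyro_sign) == 1,
            abs(anterior_sign) == 1, abs(longitudinal_sign) == 1)
  structure(list(tau = tau, fs = fs,
                 gyro_axis = gyro_axis, gyro_sign = gyro_sign,
                 accel_anterior = accel_anterior, anterior_sign = anterior_sign,
                 accel_longitudinal = accel_longitudinal,
                 longitudinal_sign = longitudinal_sign),
            class = "fusion_config")
}

#' Thigh inclination from a static accelerometer reading
#'
#' Four-quadrant angle of the gravity vector projected onto the sagittal
#' plane, mapped to the thigh-angle convention (0 = thigh vertical, flexion
#' positive). For a 3-vector the configured anterior/longitudinal channels
#' are used; a 2-column matrix `(anterior, longitudinal)` is also accepted
#' for vectorized use.
#'
#' @param accel Named numeric 3-vector (m/s^2), or an n x 2 matrix of
#'   (anterior, longitudinal) components.
#' @param config A [fusion_config()].
#' @return Inclination angle(s), rad.
#' @examples
#' accel_inclination(c(ax = 0, ay = 0, az = 9.81))           # vertical thigh
#' accel_inclination(c(ax = 9.81 * sin(0.5236), ay = 0,
#'                     az = 9.81 * cos(0.5236)))             # 30 deg flexion
#' @export
accel_inclination <- function(accel, config = fusion_config()) {
  if (is.matrix(accel)) {
    ant <- accel[, 1]; lon <- accel[, 2]
  } else {
    stopifnot(length(accel) == 3)
    if (is.null(names(accel))) names(accel) <- c("ax", "ay", "az")
    ant <- config$anterior_sign * accel[[config$accel_anterior]]
    lon <- config$longitudinal_sign * accel[[config$accel_longitudinal]]
  }
  bad <- sqrt(ant^2 + lon^2) < 1e-9
  if (!is.matrix(accel) && any(bad))
    stop("zero acceleration vector: inclination undefined")
  out <- atan2(ant, lon)
  out[bad] <- NA_real_   # vectorized path flags degenerate samples
  unname(out)
}

#' One complementary-filter update
#'
#' `theta <- lambda * (theta_prev + gyro * dt) + (1 - lambda) * inclination`
#' with `lambda = tau / (tau + dt)`: the gyroscope integral passes through a
#' high-pass, the accelerometer inclination through the complementary
#' low-pass, and the two always sum to the full signal.
#'
#' @param prev List with `t` (s) and `theta` (rad), or NULL to initialize
#'   from the accelerometer alone.
#' @param sample One IMU row: list/data.frame with `t` and the configured
#'   channels.
#' @param config A [fusion_config()].
#' @return List `t, theta, theta_dot` (the thigh state at `sample$t`).
#' @export
complementary_step <- function(prev, sample, config = fusion_config()) {
  acc <- c(ax = sample$ax, ay = sample$ay, az = sample$az)
  incl <- accel_inclination(acc, config)
  gyro <- config$gyro_sign * sample[[config$gyro_axis]]
  if (is.null(prev))
    return(list(t = sample$t, theta = incl, theta_dot = gyro))
  dt <- sample$t - prev$t
  if (!is.finite(dt) || dt <= 0) stop("non-monotone timestamps in IMU stream")
  lambda <- config$tau / (config$tau + dt)
  theta <- lambda * (prev$theta + gyro * dt) + (1 - lambda) * incl
  list(t = sample$t, theta = theta, theta_dot = gyro)
}

#' Complementary-filter an IMU stream
#'
#' Vectorized equivalent of iterating [complementary_step()] over the rows of
#' an IMU data.frame. `dt` is taken from timestamps, so dropped samples are
#' handled gracefully; when sampling is uniform the recursion is delegated to
#' `stats::filter` for speed. Samples whose accelerometer norm is ~0 fall
#' back to pure gyro integration (`lambda = 1`).
#'
#' @param imu data.frame `t, ax, ay, az, gx, gy, gz`.
#' @param config A [fusion_config()].
#' @param theta0 Initial angle, rad; defaults to the first valid
#'   accelerometer inclination.
#' @return data.frame `t, theta, theta_dot`.
#' @export
complementary_filter <- function(imu, config = fusion_config(), theta0 = NULL) {
  n <- nrow(imu)
  stopifnot(n >= 1)
  t <- imu$t
  if (n > 1 && any(diff(t) <= 0))
    stop("non-monotone timestamps in IMU stream")
  ant <- config$anterior_sign * imu[[config$accel_anterior]]
  lon <- config$longitudinal_sign * imu[[config$accel_longitudinal]]
  incl <- accel_inclination(cbind(ant, lon), config)
  gyro <- config$gyro_sign * imu[[config$gyro_axis]]

  if (is.null(theta0)) {
    first_ok <- which(!is.na(incl))[1]
    theta0 <- if (is.na(first_ok)) 0 else incl[first_ok]
  }
  if (n == 1)
    return(data.frame(t = t, theta = theta0, theta_dot = gyro))

  dt <- diff(t)
  lambda <- config$tau / (config$tau + dt)
  # degenerate accel samples: trust the gyro alone
  dead <- is.na(incl[-1])
  lambda[dead] <- 1
  incl_in <- incl[-1]
  incl_in[dead] <- 0

  drive <- lambda * gyro[-1] * dt + (1 - lambda) * incl_in
  if (max(lambda) - min(lambda) < 1e-12 && !any(dead)) {
    theta_rest <- as.numeric(stats::filter(drive, lambda[1],
                                           method = "recursive",
                                           init = theta0))
  } else {
    theta_rest <- numeric(n - 1L)
    th <- theta0
    for (k in seq_len(n - 1L)) {
      th <- lambda[k] * th + drive[k]
      theta_rest[k] <- th
    }
  }
  data.frame(t = t, theta = c(theta0, theta_rest), theta_dot = gyro)
}
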