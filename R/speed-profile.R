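#' Treadmill-style walking speed profiles
#'
#' A speed profile maps trial time to belt/walking speed by piecewise-linear
#' interpolation between breakpoints. Two stock shapes are provided:
#' `"constant"` holds one speed for the whole trial; `"ramp_profile"` holds a
#' low speed, accelerates at a fixed rate to a high speed, holds it, then
#' decelerates back and holds the low speed again - the protocol used to probe
#' estimator behaviour under walking-speed transients.
#'
#' @param kind `"constant"` or `"ramp_profile"`.
#' @param speed Speed in m/s for `kind = "constant"`.
#' @param duration Trial duration in seconds for `kind = "constant"`.
#' @param low,high Plateau speeds in m/s for the ramp profile.
#' @param accel Magnitude of the acceleration/deceleration ramp in m/s^2.
#' @param hold Duration in seconds of each constant-speed plateau.
#'
#' @return An object of class `speed_profile`: a data.frame with columns
#'   `time` (s) and `speed` (m/s), strictly increasing in `time`.
#' @examples
#' p <- make_speed_profile("ramp_profile")
#' speed_at(p, c(0, 18, 40))
#' @export
make_speed_profile <- function(kind = c("constant", "ramp_profile"),
                               speed = 1.0, duration = 60,
                               low = 0.6, high = 1.2, accel = 0.1,
                               hold = 15) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    stopifnot(is.finite(speed), speed > 0, duration > 0)
    bp <- data.frame(time = c(0, duration), speed = c(speed, speed))
  } else {
    stopifnot(low > 0, high > low, accel > 0, hold > 0)
    ramp <- (high - low) / accel
    t1 <- hold                 # end of low plateau
    t2 <- t1 + ramp            # top of acceleration
    t3 <- t2 + hold            # end of high plateau
    t4 <- t3 + ramp            # bottom of deceleration
    t5 <- t4 + hold            # trailing low plateau
    bp <- data.frame(time  = c(0, t1, t2, t3, t4, t5),
                     speed = c(low, low, high, high, low, low))
  }
  new_speed_profile(bp)
}

new_speed_profile <- function(breakpoints) {
  stopifnot(is.data.frame(breakpoints),
            all(c("time", "speed") %in% names(breakpoints)))
  if (any(diff(breakpoints$time) <= 0))
    stop("speed profile breakpoint times must be strictly increasing")
  if (any(!is.finite(breakpoints$speed)))
    stop("speed profile speeds must be finite")
  if (any(breakpoints$speed < 0.3 | breakpoints$speed > 2.5))
    stop("speed profile speeds must lie in [0.3, 2.5] m/s")
  structure(breakpoints[c("time", "speed")], class = c("speed_profile", "data.frame"))
}

#' Evaluate a speed profile
#'
#' @param profile A [make_speed_profile()] object.
#' @param t Numeric vector of times in seconds; times outside the breakpoint
#'   range are clamped to the first/last speed.
#' @return Speeds in m/s, same length as `t`.
#' @export
speed_at <- function(profile, t) {
  stopifnot(inherits(profile, "speed_profile"), all(is.finite(t)))
  stats::approx(profile$time, profile$speed, xout = t, rule = 2)$y
}

#' Total duration covered by a speed profile
#' @param profile A [make_speed_profile()] object.
#' @return Last breakpoint time in seconds.
#' @export
profile_duration <- function(profile) {
  stopifnot(inherits(profile, "speed_profile"))
  max(profile$time)
}
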