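#' Gait frequency from stride period
#'
#' The dominant angular frequency of thigh kinematics equals `2*pi/T_stride`,
#' where `T_stride` is the time between two consecutive identical gait events
#' of the same foot.
#'
#' @param T_stride Stride period, s (> 0).
#' @return Gait frequency, rad/s.
#' @export
gait_frequency <- function(T_stride) {
  if (any(!is.finite(T_stride)) || any(T_stride <= 0))
    stop("stride period must be positive and finite")
  2 * pi / T_stride
}

#' Adaptive cutoff frequency
#'
#' The gait-frequency-adaptive filter (GFAF) ties its cutoff to the current
#' gait frequency: `omega_c = alpha * omega_gait`. Because the cutoff scales
#' with the signal's fundamental, the filter's phase lag at that fundamental
#' is the speed-independent constant `n * atan(1/alpha)`.
#'
#' @param omega_gait Gait frequency, rad/s (> 0).
#' @param alpha Proportional factor (> 0).
#' @return Cutoff frequency, rad/s.
#' @export
gfaf_cutoff <- function(omega_gait, alpha) {
  stopifnot(all(omega_gait > 0), alpha > 0)
  alpha * omega_gait
}

#' Phase lag of an n-stage first-order low-pass cascade
#'
#' For the cascade `(omega_c / (j*omega + omega_c))^n` the phase response is
#' `-n * atan(omega / omega_c)` (negative = lag).
#'
#' @param omega Signal frequency, rad/s.
#' @param omega_c Cutoff frequency, rad/s (> 0).
#' @param n Filter order (stages).
#' @return Phase, rad (<= 0).
#' @export
lpf_phase_lag <- function(omega, omega_c, n) {
  stopifnot(all(omega_c > 0), n >= 1)
  -n * atan(omega / omega_c)
}

#' Closed-form GFAF lag at the gait frequency
#'
#' Substituting `omega = omega_gait` and `omega_c = alpha * omega_gait` into
#' the cascade's phase response collapses it to `n * atan(1/alpha)`,
#' independent of the gait frequency itself. This is the constant the phase
#' compensation step adds back.
#'
#' @param n Filter order.
#' @param alpha Proportional factor (> 0).
#' @return Lag magnitude, rad (>= 0).
#' @examples
#' gfaf_lag(2, 2.5)   # 0.761 rad
#' @export
gfaf_lag <- function(n, alpha) {
  stopifnot(n >= 1, alpha > 0)
  n * atan(1 / alpha)
}

#' Streaming GFAF state
#'
#' @param n Number of cascaded first-order stages (>= 1).
#' @param init Initial value of every stage output.
#' @return A list of class `gfaf_state` with `y` (stage outputs).
#' @export
gfaf_state <- function(n = 2, init = 0) {
  stopifnot(n >= 1)
  structure(list(y = rep(init, n), n = as.integer(n)), class = "gfaf_state")
}

#' One sample through the backward-Euler GFAF cascade
#'
#' Each stage applies `y[k] = (y[k-1] + omega_c*Ts*x[k]) / (1 + omega_c*Ts)`,
#' the backward-Euler discretization of a first-order low-pass; the cutoff is
#' re-read every call so it may track the gait frequency sample by sample
#' with state carried over (bumpless cutoff changes).
#'
#' @param state A [gfaf_state()].
#' @param x Input sample.
#' @param omega_c Cutoff, rad/s (> 0).
#' @param Ts Sample interval, s (> 0).
#' @return List `state` (updated), `y` (last stage output).
#' @export
gfaf_step <- function(state, x, omega_c, Ts) {
  stopifnot(inherits(state, "gfaf_state"), Ts > 0, omega_c > 0)
  if (!is.finite(x)) stop("non-finite input to gfaf_step")
  wT <- omega_c * Ts
  u <- x
  for (i in seq_len(state$n)) {
    u <- (state$y[i] + wT * u) / (1 + wT)
    state$y[i] <- u
  }
  list(state = state, y = u)
}

#' Filter a whole stream through the GFAF cascade
#'
#' Offline/vectorized equivalent of iterating [gfaf_step()]. With a scalar
#' (constant) cutoff each stage is a constant-coefficient recursion delegated
#' to `stats::filter`; a per-sample cutoff vector falls back to an explicit
#' loop and produces the identical sample-by-sample result.
#'
#' @param x Numeric input stream.
#' @param omega_c Cutoff in rad/s: scalar, or one value per sample.
#' @param n Filter order.
#' @param fs Sampling frequency, Hz.
#' @param init Initial stage value (default 0, matching a quiescent filter).
#' @return Filtered stream, same length as `x`.
#' @export
gfaf_filter <- function(x, omega_c, n = 2, fs = 1000, init = 0) {
  stopifnot(n >= 1, fs > 0, all(is.finite(x)), all(omega_c > 0))
  Ts <- 1 / fs
  if (length(omega_c) == 1) {
    wT <- omega_c * Ts
    b <- wT / (1 + wT)
    a <- 1 / (1 + wT)
    y <- x
    for (i in seq_len(n))
      y <- as.numeric(stats::filter(b * y, a, method = "recursive",
                                    init = init))
    return(y)
  }
  stopifnot(length(omega_c) == length(x))
  wT <- omega_c * Ts
  y <- numeric(length(x))
  st <- rep(init, n)
  for (k in seq_along(x)) {
    u <- x[k]
    for (i in seq_len(n)) {
      u <- (st[i] + wT[k] * u) / (1 + wT[k])
      st[i] <- u
    }
    y[k] <- u
  }
  y
}

#' Backward-difference differentiation
#'
#' `theta_dot[k] = (theta[k] - theta[k-1]) / Ts`, the strictly causal
#' derivative used throughout the online pipeline; the first sample's
#' derivative is defined as 0.
#'
#' @param x Numeric stream (length >= 2), uniformly sampled.
#' @param Ts Sample interval, s.
#' @return Derivative stream, same length as `x`.
#' @export
differentiate <- function(x, Ts) {
  stopifnot(Ts > 0)
  if (length(x) < 2) stop("need at least 2 samples to differentiate")
  c(0, diff(x) / Ts)
}
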