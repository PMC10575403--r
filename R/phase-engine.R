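#' Phase-engine configuration
#'
#' Collects every tunable of the online estimator. Defaults reproduce the
#' reference pipeline: order-2 gait-frequency-adaptive filter with
#' `alpha = 2.5` (lag `2*atan(1/2.5) = 0.761` rad, compensated after phase
#' computation), normalization-parameter smoothing pole `a = 0.98` applied at
#' the sample rate, maximum-flexion stride segmentation with a refractory
#' window of `0.4 * T_stride`, and stride periods clamped to the physiologic
#' cadence band `[0.4, 2.5]` s.
#'
#' Bootstrap (the first strides, before any maximum-flexion interval has been
#' observed) uses `T0` as the stride period and the prior normalization
#' parameters below; output is flagged unconverged until two full strides
#' have completed.
#'
#' @param fs Sampling frequency, Hz.
#' @param n GFAF order (first-order stages).
#' @param alpha GFAF proportional factor (cutoff = alpha * gait frequency).
#' @param pole IIR smoothing pole `a` in [0, 1) for normalization parameters
#'   and the gait frequency; 0 disables smoothing.
#' @param fusion A [fusion_config()].
#' @param T0 Bootstrap stride period, s.
#' @param prior_A_theta,prior_theta_o Bootstrap normalization priors, rad.
#' @param prior_theta_dot_o Bootstrap velocity center, rad/s.
#' @param refractory Fraction of `T_stride` during which a new
#'   maximum-flexion event cannot fire.
#' @param T_clamp Length-2 clamp on stride period, s.
#' @param cutoff_clamp Length-2 clamp on the adaptive cutoff, rad/s.
#' @param cutoff_hz Fixed cutoff in Hz for the LPF baseline.
#' @param unconverged_strides Completed strides before output is flagged
#'   converged.
#' @return A list of class `phase_config`.
#' @export
phase_config <- function(fs = 1000, n = 2, alpha = 2.5, pole = 0.98,
                         fusion = fusion_config(fs = fs),
                         T0 = 1.1,
                         prior_A_theta = 0.35, prior_theta_o = 0,
                         prior_theta_dot_o = 0,
                         refractory = 0.4,
                         T_clamp = c(0.4, 2.5),
                         cutoff_clamp = c(0.5, 50),
                         cutoff_hz = 1.5,
                         unconverged_strides = 2) {
  stopifnot(fs > 0, n >= 1, alpha > 0, pole >= 0, pole < 1,
            T0 > 0, prior_A_theta > 0, refractory > 0, refractory < 1,
            length(T_clamp) == 2, T_clamp[1] > 0, T_clamp[2] > T_clamp[1],
            length(cutoff_clamp) == 2, cutoff_clamp[2] > cutoff_clamp[1],
            cutoff_hz > 0)
  structure(list(fs = fs, n = as.integer(n), alpha = alpha, pole = pole,
                 fusion = fusion, T0 = T0,
                 prior_A_theta = prior_A_theta, prior_theta_o = prior_theta_o,
                 prior_theta_dot_o = prior_theta_dot_o,
                 prior_A_theta_dot = 2 * pi * prior_A_theta / T0,
                 refractory = refractory, T_clamp = T_clamp,
                 cutoff_clamp = cutoff_clamp, cutoff_hz = cutoff_hz,
                 unconverged_strides = as.integer(unconverged_strides)),
            class = "phase_config")
}

#' Per-stride normalization parameters from extrema
#'
#' Centers are midpoints and amplitudes half-ranges of the angle and angular
#' velocity extrema observed over the previous stride.
#'
#' @param theta_max,theta_min Stride extrema of the angle, rad.
#' @param theta_dot_max,theta_dot_min Stride extrema of the velocity, rad/s.
#' @return List `theta_o, theta_dot_o, A_theta, A_theta_dot`.
#' @export
update_stride_params <- function(theta_max, theta_min,
                                 theta_dot_max, theta_dot_min) {
  if (theta_max < theta_min || theta_dot_max < theta_dot_min)
    stop("extrema out of order: max < min")
  A_theta <- (theta_max - theta_min) / 2
  A_theta_dot <- (theta_dot_max - theta_dot_min) / 2
  if (A_theta <= 1e-6 || A_theta_dot <= 1e-6)
    stop2_degenerate("degenerate (non-walking) stride: zero amplitude")
  list(theta_o = (theta_max + theta_min) / 2,
       theta_dot_o = (theta_dot_max + theta_dot_min) / 2,
       A_theta = A_theta, A_theta_dot = A_theta_dot)
}

stop2_degenerate <- function(msg) {
  stop(structure(class = c("gaitphase_degenerate_stride", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' One step of the normalization-parameter smoother
#'
#' First-order IIR low-pass `y[k] = a*y[k-1] + (1-a)*target`, run at the
#' sample rate with the target held constant between stride updates. This is
#' what removes the phase-portrait discontinuity that a raw per-stride
#' parameter update would cause.
#'
#' @param current Current smoothed value.
#' @param target Held per-stride target.
#' @param a Pole in [0, 1).
#' @return Updated smoothed value.
#' @export
smooth_param_step <- function(current, target, a) {
  stopifnot(a >= 0, a < 1)
  a * current + (1 - a) * target
}

#' Normalize angle and velocity onto the unit portrait
#'
#' `theta_n = (theta - theta_o)/A_theta`,
#' `theta_dot_n = (theta_dot - theta_dot_o)/A_theta_dot`. With exact
#' parameters a sinusoidal gait maps onto the unit circle centered at the
#' origin.
#'
#' @param theta,theta_dot Signals (rad, rad/s); vectorized.
#' @param params List with `theta_o, theta_dot_o, A_theta, A_theta_dot`
#'   (scalars or per-sample vectors).
#' @return List `theta_n, theta_dot_n`.
#' @export
normalize_portrait <- function(theta, theta_dot, params) {
  if (any(params$A_theta <= 0) || any(params$A_theta_dot <= 0))
    stop("normalization amplitudes must be positive")
  list(theta_n = (theta - params$theta_o) / params$A_theta,
       theta_dot_n = (theta_dot - params$theta_dot_o) / params$A_theta_dot)
}

#' Gait phase from the normalized phase portrait
#'
#' Clockwise angle of the point `(theta_n, theta_dot_n)` with respect to the
#' +x axis, in [0, 2*pi): 0 at maximum flexion `(1, 0)`, pi/2 at `(0, -1)`,
#' pi at maximum extension `(-1, 0)`, 3*pi/2 at `(0, 1)`. Realized as
#' `atan2(-theta_dot_n, theta_n) mod 2*pi`, which equals the three-branch
#' arctangent definition everywhere while keeping `theta_n = 0` well-defined.
#'
#' @param theta_n,theta_dot_n Normalized coordinates; vectorized.
#' @return Phase, rad in [0, 2*pi); `NA` at the origin (vectorized input).
#' @export
portrait_phase <- function(theta_n, theta_dot_n) {
  r2 <- theta_n^2 + theta_dot_n^2
  if (length(theta_n) == 1 && (!is.finite(r2) || r2 < 1e-18))
    stop("phase undefined at the portrait origin")
  phi <- atan2(-theta_dot_n, theta_n) %% (2 * pi)
  phi[r2 < 1e-18] <- NA_real_
  phi
}

#' Compensate the constant GFAF lag
#'
#' Adds the closed-form lag `n * atan(1/alpha)` back to the estimated phase,
#' wrapping modulo 2*pi. Valid precisely because the adaptive cutoff makes
#' the lag at the gait frequency independent of the gait frequency.
#'
#' @param phi Phase, rad in [0, 2*pi); vectorized.
#' @param n,alpha GFAF order and proportional factor.
#' @return Compensated phase, rad in [0, 2*pi).
#' @export
compensate_phase <- function(phi, n, alpha) {
  (phi + gfaf_lag(n, alpha)) %% (2 * pi)
}

#' Convert phase from radians to percent of gait cycle
#'
#' @param phi Phase, rad in [0, 2*pi).
#' @return Percent in [0, 100): `50 * phi / pi`.
#' @export
phase_to_percent <- function(phi) 50 * phi / pi

#' Streaming stride-segmentation state
#'
#' Running state of the maximum-flexion detector and normalization-parameter
#' tracker: last event time, stride period and gait frequency, current-stride
#' extrema, held per-stride (raw) parameters and their smoothed versions, and
#' the completed-stride count.
#'
#' @param config A [phase_config()].
#' @param t0 Time of the first sample, s (starts the refractory window).
#' @return A list of class `stride_state`.
#' @export
stride_state <- function(config = phase_config(), t0 = 0) {
  prior <- list(theta_o = config$prior_theta_o,
                theta_dot_o = config$prior_theta_dot_o,
                A_theta = config$prior_A_theta,
                A_theta_dot = config$prior_A_theta_dot)
  structure(list(t_last = t0, T_stride = config$T0,
                 omega_gait = 2 * pi / config$T0,
                 th_max = -Inf, th_min = Inf,
                 td_max = -Inf, td_min = Inf,
                 td_prev = NA_real_,
                 raw_params = prior, smoothed = prior,
                 omega_smoothed = 2 * pi / config$T0,
                 event_count = 0L, stride_count = 0L),
            class = "stride_state")
}

#' Maximum-flexion event detection (one sample)
#'
#' Fires when the (filtered) angular velocity crosses from positive to
#' negative while the angle is above its smoothed center - i.e. at maximum
#' flexion, where the signal is impact-free - subject to a refractory window
#' of `refractory * T_stride` since the previous event. On firing, the
#' elapsed interval becomes the new stride period (clamped), the
#' current-stride extrema freeze into the held normalization parameters, and
#' extrema tracking restarts. Degenerate strides (zero amplitude) leave the
#' previous parameters in place.
#'
#' @param state A [stride_state()].
#' @param theta,theta_dot Current (filtered) angle and velocity.
#' @param t Current time, s.
#' @param config A [phase_config()].
#' @return List `state` (updated), `event` (logical).
#' @export
detect_max_flexion <- function(state, theta, theta_dot, t,
                               config = phase_config()) {
  # extrema tracking for the running stride
  state$th_max <- max(state$th_max, theta)
  state$th_min <- min(state$th_min, theta)
  state$td_max <- max(state$td_max, theta_dot)
  state$td_min <- min(state$td_min, theta_dot)

  fired <- FALSE
  if (!is.na(state$td_prev) && state$td_prev > 0 && theta_dot <= 0 &&
      theta > state$smoothed$theta_o &&
      (t - state$t_last) > config$refractory * state$T_stride) {
    fired <- TRUE
    if (state$event_count >= 1L) {
      Tn <- min(max(t - state$t_last, config$T_clamp[1]), config$T_clamp[2])
      state$T_stride <- Tn
      state$omega_gait <- 2 * pi / Tn
      new_p <- tryCatch(
        update_stride_params(state$th_max, state$th_min,
                             state$td_max, state$td_min),
        gaitphase_degenerate_stride = function(e) NULL)
      if (!is.null(new_p)) state$raw_params <- new_p
      state$stride_count <- state$stride_count + 1L
    }
    state$event_count <- state$event_count + 1L
    state$t_last <- t
    state$th_max <- theta; state$th_min <- theta
    state$td_max <- theta_dot; state$td_min <- theta_dot
  }
  state$td_prev <- theta_dot
  list(state = state, event = fired)
}

# ---------------------------------------------------------------------------
# Full streaming engine. One pass over the fused angle stream; the per-sample
# logic mirrors gfaf_step / detect_max_flexion / smooth_param_step exactly
# (equivalence is enforced by tests) but is inlined for speed.
# ---------------------------------------------------------------------------
run_engine <- function(fused, config, method = c("gfaf", "lpf", "tbe")) {
  method <- match.arg(method)
  t <- fused$t
  theta_raw <- fused$theta
  nsamp <- length(t)
  stopifnot(nsamp >= 2)
  dt <- diff(t)
  if (any(dt <= 0)) stop("non-monotone timestamps")

  a <- config$pole
  nf <- config$n
  alpha <- config$alpha
  refrac <- config$refractory
  Tlo <- config$T_clamp[1]; Thi <- config$T_clamp[2]
  wlo <- config$cutoff_clamp[1]; whi <- config$cutoff_clamp[2]
  w_fixed <- 2 * pi * config$cutoff_hz   # LPF baseline cutoff

  # state
  T_stride <- config$T0
  omega_target <- 2 * pi / T_stride
  omega_s <- omega_target
  tg <- c(config$prior_theta_o, config$prior_theta_dot_o,
          config$prior_A_theta, config$prior_A_theta_dot)  # held targets
  sm <- tg                                                 # smoothed params
  stages <- rep(theta_raw[1], nf)  # init filter at first sample: no start jump
  th_max <- -Inf; th_min <- Inf; td_max <- -Inf; td_min <- Inf
  td_prev <- NA_real_
  t_last <- t[1]
  event_count <- 0L; stride_count <- 0L
  T_prev_done <- NA_real_          # last completed stride period (TBE)

  thf <- numeric(nsamp); td <- numeric(nsamp)
  p1 <- numeric(nsamp); p2 <- numeric(nsamp)
  p3 <- numeric(nsamp); p4 <- numeric(nsamp)
  stride_id <- integer(nsamp)
  tbe_pct <- if (method == "tbe") rep(NA_real_, nsamp) else NULL

  filtering <- method != "tbe"
  thf[1] <- theta_raw[1]; td[1] <- 0
  p1[1] <- sm[1]; p2[1] <- sm[2]; p3[1] <- sm[3]; p4[1] <- sm[4]

  for (k in 2:nsamp) {
    Ts <- dt[k - 1]
    # --- gait-frequency smoothing and adaptive cutoff
    if (a > 0) omega_s <- a * omega_s + (1 - a) * omega_target
    else omega_s <- omega_target

    if (filtering) {
      w <- if (method == "gfaf") {
        wc <- alpha * omega_s
        if (wc < wlo) wlo else if (wc > whi) whi else wc
      } else w_fixed
      wT <- w * Ts
      u <- theta_raw[k]
      for (i in seq_len(nf)) {
        u <- (stages[i] + wT * u) / (1 + wT)
        stages[i] <- u
      }
      thf[k] <- u
    } else {
      thf[k] <- theta_raw[k]
    }
    td[k] <- (thf[k] - thf[k - 1]) / Ts

    # --- parameter smoothing (targets held between stride updates)
    if (a > 0) sm <- a * sm + (1 - a) * tg else sm <- tg

    # --- extrema tracking
    if (thf[k] > th_max) th_max <- thf[k]
    if (thf[k] < th_min) th_min <- thf[k]
    if (td[k] > td_max) td_max <- td[k]
    if (td[k] < td_min) td_min <- td[k]

    # --- maximum-flexion event
    if (!is.na(td_prev) && td_prev > 0 && td[k] <= 0 &&
        thf[k] > sm[1] && (t[k] - t_last) > refrac * T_stride) {
      if (event_count >= 1L) {
        Tn <- t[k] - t_last
        if (Tn < Tlo) Tn <- Tlo else if (Tn > Thi) Tn <- Thi
        T_prev_done <- Tn
        T_stride <- Tn
        omega_target <- 2 * pi / Tn
        A_th <- (th_max - th_min) / 2
        A_td <- (td_max - td_min) / 2
        if (A_th > 1e-6 && A_td > 1e-6)
          tg <- c((th_max + th_min) / 2, (td_max + td_min) / 2, A_th, A_td)
        stride_count <- stride_count + 1L
      }
      event_count <- event_count + 1L
      t_last <- t[k]
      th_max <- thf[k]; th_min <- thf[k]
      td_max <- td[k]; td_min <- td[k]
    }
    td_prev <- td[k]
    stride_id[k] <- stride_count

    if (method == "tbe" && !is.na(T_prev_done))
      tbe_pct[k] <- min(100 * (t[k] - t_last) / T_prev_done, 100 - 1e-9)

    p1[k] <- sm[1]; p2[k] <- sm[2]; p3[k] <- sm[3]; p4[k] <- sm[4]
  }

  converged <- stride_id >= config$unconverged_strides

  if (method == "tbe") {
    phi <- tbe_pct * pi / 50
    out <- data.frame(t = t, phi_rad = phi, phi_comp_rad = phi,
                      phi_pct = tbe_pct, stride_id = stride_id,
                      converged = converged & !is.na(tbe_pct))
    return(out)
  }

  norm <- normalize_portrait(thf, td,
                             list(theta_o = p1, theta_dot_o = p2,
                                  A_theta = p3, A_theta_dot = p4))
  phi <- portrait_phase(norm$theta_n, norm$theta_dot_n)
  phi_comp <- if (method == "gfaf") compensate_phase(phi, nf, alpha) else phi
  out <- data.frame(t = t, theta_f = thf, theta_dot_f = td,
                    phi_rad = phi, phi_comp_rad = phi_comp,
                    phi_pct = phase_to_percent(phi_comp),
                    stride_id = stride_id,
                    converged = converged & !is.na(phi))
  # smoothed normalization parameters, one row per sample
  attr(out, "norm_params") <- data.frame(theta_o = p1, theta_dot_o = p2,
                                         A_theta = p3, A_theta_dot = p4)
  out
}

#' Run the full online gait-phase pipeline on an IMU stream
#'
#' Chains complementary-filter sensor fusion, the gait-frequency-adaptive
#' low-pass filter, backward-difference differentiation, maximum-flexion
#' stride segmentation, IIR-smoothed normalization, phase-portrait phase
#' computation, and constant lag compensation - strictly causally (sample k
#' uses only samples up to k).
#'
#' @param imu data.frame `t, ax, ay, az, gx, gy, gz` with strictly increasing
#'   timestamps (see [read_imu_csv()]).
#' @param config A [phase_config()].
#' @param method `"gfaf"` (proposed), `"lpf"` (fixed-cutoff low-pass
#'   baseline, uncompensated - its lag varies with speed so no constant can
#'   compensate it), or `"tbe"` (time-based estimation baseline:
#'   elapsed time since the last maximum-flexion event divided by the
#'   previous stride period, saturating just below 100 %).
#' @return data.frame `t, phi_rad, phi_comp_rad, phi_pct, stride_id,
#'   converged` (plus `theta_f, theta_dot_f` for the portrait methods).
#'   `phi_rad` is the raw portrait phase, `phi_comp_rad` the
#'   delay-compensated phase, `phi_pct` the compensated phase in percent.
#'   Samples at the portrait origin (e.g. an all-zero stream) have `NA` phase
#'   and `converged = FALSE`. For the portrait methods the per-sample
#'   smoothed normalization parameters are attached as attribute
#'   `"norm_params"`.
#' @examples
#' tr <- synth_trial(1.0, duration = 8, params = gait_model_params(seed = 1),
#'                   fs = 500)
#' ph <- process_stream(tr$imu, phase_config(fs = 500))
#' tail(ph$phi_pct)
#' @export
process_stream <- function(imu, config = phase_config(),
                           method = c("gfaf", "lpf", "tbe")) {
  method <- match.arg(method)
  fused <- complementary_filter(imu, config$fusion)
  run_engine(fused, config, method)
}
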