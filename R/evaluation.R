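#' Ground-truth gait events from vertical GRF
#'
#' Heel strike fires when the vertical ground reaction force crosses upward
#' through 10 % of body weight; toe-off when it crosses downward through the
#' same threshold. Sub-sample timing by linear interpolation between the
#' bracketing samples.
#'
#' @param grf data.frame `t, vgrf` (s, N), `vgrf >= 0`.
#' @param body_weight Body weight, N (> 0).
#' @param threshold_frac Threshold as a fraction of body weight.
#' @return List `hs_times`, `to_times` (s).
#' @export
detect_events_grf <- function(grf, body_weight, threshold_frac = 0.1) {
  stopifnot(body_weight > 0, nrow(grf) >= 1)
  if (nrow(grf) < 2) return(list(hs_times = numeric(0), to_times = numeric(0)))
  thr <- threshold_frac * body_weight
  v <- grf$vgrf; t <- grf$t
  below <- v < thr
  up <- which(below[-length(v)] & !below[-1])      # v[k] < thr <= v[k+1]
  dn <- which(!below[-length(v)] & below[-1])      # v[k] >= thr > v[k+1]
  cross_time <- function(k) {
    t[k] + (thr - v[k]) / (v[k + 1] - v[k]) * (t[k + 1] - t[k])
  }
  list(hs_times = vapply(up, cross_time, numeric(1)),
       to_times = vapply(dn, cross_time, numeric(1)))
}

#' Circular mean and SD of phases in percent of cycle
#'
#' Phases live on a circle of circumference 100; deviations are unwrapped
#' about the circular mean into (-50, 50] before the sample SD, so events
#' near the 0/100 wrap are handled correctly.
#'
#' @param pct Numeric vector of phases in [0, 100).
#' @return List `mean` (in [0, 100)), `sd` (sample SD, percent), `n`.
#' @export
circular_phase_stats <- function(pct) {
  pct <- pct[!is.na(pct)]
  n <- length(pct)
  if (n == 0) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  ang <- pct * 2 * pi / 100
  m <- atan2(mean(sin(ang)), mean(cos(ang))) %% (2 * pi) * 100 / (2 * pi)
  dev <- (pct - m + 50) %% 100 - 50
  list(mean = m, sd = if (n > 1) stats::sd(dev) else 0, n = n)
}

#' Phase statistics at gait events
#'
#' Samples an estimated phase stream (nearest sample) at given event times
#' and returns circular-safe mean and sample SD - the repeatability metric:
#' a good estimator reports the same phase every time the same physical
#' event recurs.
#'
#' @param phase data.frame from [process_stream()] (columns `t, phi_pct`,
#'   optionally `converged`).
#' @param event_times Event times, s; must fall inside the stream's span.
#' @param event Label stored in the output (e.g. `"heel_strike"`).
#' @param converged_only Drop events where the estimator was not converged.
#' @return One-row data.frame `event, mean_phase, std_phase, n_strides`.
#' @export
event_phase_stats <- function(phase, event_times, event = "event",
                              converged_only = TRUE) {
  if (!length(event_times))
    return(data.frame(event = event, mean_phase = NA_real_,
                      std_phase = NA_real_, n_strides = 0L))
  if (min(event_times) < min(phase$t) || max(event_times) > max(phase$t))
    stop("event time outside phase stream span")
  idx <- findInterval(event_times, phase$t)
  # nearest sample, not floor
  nxt <- pmin(idx + 1L, nrow(phase))
  pick_next <- (phase$t[nxt] - event_times) < (event_times - phase$t[idx])
  idx[pick_next] <- nxt[pick_next]
  pct <- phase$phi_pct[idx]
  if (converged_only && "converged" %in% names(phase))
    pct <- pct[phase$converged[idx]]
  s <- circular_phase_stats(pct)
  data.frame(event = event, mean_phase = s$mean, std_phase = s$sd,
             n_strides = s$n)
}

#' Cross-spectral phase lag at a known fundamental
#'
#' Projects both streams onto the complex exponential at the fundamental
#' frequency (over a whole number of periods, so no window leakage) and
#' returns the phase of the input-output cross-spectrum at that bin: how far
#' `y` lags `x` in radians, reported as a positive magnitude with the signed
#' value in attribute `"signed"`. Swapping the streams flips the sign.
#'
#' @param x,y Equal-length input/output streams (transient already trimmed).
#' @param f0 Fundamental frequency, Hz.
#' @param fs Sampling frequency, Hz.
#' @return Lag magnitude, rad; attribute `"signed"` carries the sign.
#' @export
measure_phase_delay <- function(x, y, f0, fs) {
  stopifnot(length(x) == length(y), fs > 0, f0 > 0)
  n_per <- floor(length(x) * f0 / fs)
  if (n_per < 1) stop("fundamental below frequency resolution of the stream")
  m <- floor(n_per * fs / f0)             # whole periods only
  k <- seq_len(m)
  e <- exp(-2i * pi * f0 * (k - 1) / fs)
  X <- sum(x[k] * e)
  Y <- sum(y[k] * e)
  signed <- Arg(X * Conj(Y))              # > 0 when y lags x
  structure(abs(signed), signed = signed)
}

#' Dominant frequency of a signal (Welch periodogram)
#'
#' Detrends the signal, averages Hann-windowed periodograms over 4 segments
#' with 50 % overlap, and returns the frequency of the largest non-DC peak.
#' The peak-to-median spectral ratio gates confidence: below 5 the estimate
#' is flagged unreliable (attribute `"confident"`), as for aperiodic input.
#'
#' @param x Signal (>= a few seconds of data).
#' @param fs Sampling frequency, Hz.
#' @param n_segments,overlap Welch parameters.
#' @return Dominant frequency, Hz, with attributes `"confident"` (logical)
#'   and `"peak_ratio"`.
#' @export
dominant_frequency <- function(x, fs, n_segments = 4, overlap = 0.5) {
  stopifnot(fs > 0, length(x) >= 16)
  x <- x - mean(x)
  if (stats::sd(x) < 1e-12) stop("constant signal has no dominant frequency")
  L <- floor(length(x) / (1 + (n_segments - 1) * (1 - overlap)))
  step <- floor(L * (1 - overlap))
  win <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))   # Hann
  starts <- seq(1, length(x) - L + 1, by = step)[seq_len(n_segments)]
  starts <- starts[!is.na(starts)]
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  nb <- floor(L / 2)
  pw <- acc[2:(nb + 1)]                    # drop DC bin
  freqs <- (1:nb) * fs / L
  i <- which.max(pw)
  ratio <- pw[i] / stats::median(pw)
  structure(freqs[i], confident = ratio >= 5, peak_ratio = ratio)
}

#' Relative root-mean-square error between frequency estimates, in percent
#'
#' @param estimated,measured Equal-length vectors, Hz; `measured` is the
#'   reference and must be nonzero.
#' @return `100 * sqrt(mean(((est - meas)/meas)^2))`.
#' @export
frequency_rmse <- function(estimated, measured) {
  if (length(estimated) != length(measured)) stop("length mismatch")
  if (any(measured == 0)) stop("zero reference frequency")
  100 * sqrt(mean(((estimated - measured) / measured)^2))
}

#' Build a multi-speed set of synthetic trials
#'
#' One constant-speed trial per requested speed, emulating a treadmill
#' protocol sweeping the walking-speed range; per-trial seeds derive from
#' `seed` so the set is reproducible.
#'
#' @param speeds Speeds, m/s.
#' @param duration Per-trial duration, s.
#' @param fs Sampling frequency, Hz.
#' @param seed Master seed.
#' @param params Template [gait_model_params()]; its seed is replaced per
#'   trial.
#' @return List of [synth_trial()] objects, named by speed.
#' @export
make_trial_set <- function(speeds = seq(0.6, 1.6, by = 0.2), duration = 30,
                           fs = 1000, seed = 1L,
                           params = gait_model_params()) {
  trials <- lapply(seq_along(speeds), function(i) {
    params$seed <- as.integer(seed + 1000L * i)
    synth_trial(speeds[i], params = params, fs = fs, duration = duration)
  })
  names(trials) <- sprintf("%.1f", speeds)
  trials
}

#' Event-phase comparison report across estimation methods
#'
#' Runs each method on each trial, samples the estimated phase at the
#' ground-truth heel-strike and toe-off times (from the trial's exact event
#' times, or from its vGRF stream via [detect_events_grf()]), pools events
#' over all trials/speeds, and reports per-method circular mean and SD plus
#' the percent reduction in SD of the adaptive method relative to each
#' baseline: `100 * (sd_base - sd_gfaf) / sd_base`.
#'
#' @param trials List of [synth_trial()] objects (see [make_trial_set()]).
#' @param methods Character subset of `c("gfaf", "lpf", "tbe")`; must
#'   contain at least 2, including `"gfaf"` for the reduction rows.
#' @param config A [phase_config()].
#' @param skip_strides Leading strides per trial excluded as convergence
#'   transient.
#' @param events_from `"truth"` uses the generator's exact event times,
#'   `"grf"` re-detects them from the synthetic vGRF.
#' @return List `stats` (data.frame `method, event, mean_phase, std_phase,
#'   n_strides`), `reduction` (data.frame `baseline, event, reduction_pct`),
#'   and `per_trial` (per-speed stats for trend analysis: adds a `speed`
#'   column).
#' @export
compare_report <- function(trials, methods = c("gfaf", "lpf", "tbe"),
                           config = phase_config(), skip_strides = 3,
                           events_from = c("truth", "grf")) {
  events_from <- match.arg(events_from)
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) < 2) stop("need at least two methods to compare")

  per_trial <- list()
  pool <- list()   # pooled per-event phase samples, keyed method|event
  for (m in methods) {
    for (nm in names(trials)) {
      tr <- trials[[nm]]
      ph <- process_stream(tr$imu, config, method = m)
      if (events_from == "truth") {
        ev <- list(hs_times = tr$hs_times, to_times = tr$to_times)
      } else {
        ev <- detect_events_grf(tr$vgrf, tr$body_weight)
      }
      t_conv <- skip_time(ph, skip_strides)
      for (e in c("heel_strike", "toe_off")) {
        times <- if (e == "heel_strike") ev$hs_times else ev$to_times
        times <- times[times >= t_conv & times <= max(ph$t)]
        st <- event_phase_stats(ph, times, event = e)
        st$method <- m; st$speed <- as.numeric(nm)
        per_trial[[length(per_trial) + 1L]] <- st
        key <- paste(m, e, sep = "|")
        pool[[key]] <- c(pool[[key]], sample_event_phases(ph, times))
      }
    }
  }
  per_trial <- do.call(rbind, per_trial)

  # pooled over speeds
  pooled <- list()
  for (m in methods) {
    for (e in c("heel_strike", "toe_off")) {
      s <- circular_phase_stats(pool[[paste(m, e, sep = "|")]])
      pooled[[length(pooled) + 1L]] <-
        data.frame(method = m, event = e, mean_phase = s$mean,
                   std_phase = s$sd, n_strides = s$n)
    }
  }
  pooled <- do.call(rbind, pooled)

  reduction <- NULL
  if ("gfaf" %in% methods) {
    for (b in setdiff(methods, "gfaf")) {
      for (e in c("heel_strike", "toe_off")) {
        sb <- pooled$std_phase[pooled$method == b & pooled$event == e]
        sg <- pooled$std_phase[pooled$method == "gfaf" & pooled$event == e]
        reduction <- rbind(reduction,
                           data.frame(baseline = b, event = e,
                                      reduction_pct = 100 * (sb - sg) / sb))
      }
    }
  }
  list(stats = pooled, reduction = reduction, per_trial = per_trial)
}

# time after which `skip_strides` strides have completed
skip_time <- function(phase, skip_strides) {
  i <- which(phase$stride_id >= skip_strides)[1]
  if (is.na(i)) max(phase$t) else phase$t[i]
}

# converged per-event phase samples from one phase stream
sample_event_phases <- function(ph, times) {
  if (!length(times)) return(numeric(0))
  idx <- findInterval(times, ph$t)
  idx[idx < 1L] <- 1L
  nxt <- pmin(idx + 1L, nrow(ph))
  pick <- (ph$t[nxt] - times) < (times - ph$t[idx])
  idx[pick] <- nxt[pick]
  keep <- ph$converged[idx] & !is.na(ph$phi_pct[idx])
  ph$phi_pct[idx[keep]]
}
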