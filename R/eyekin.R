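# Eye-trace preprocessing, adaptive-threshold saccade detection, and trial
# scoring.

# Zero-phase FIR low-pass with constant edge padding (signal::filtfilt alone
# rings at the trace boundaries).
zero_phase_fir <- function(x, b) {
  np <- 3L * length(b)
  xp <- c(rep(x[1], np), x, rep(x[length(x)], np))
  y <- signal::filtfilt(b, 1, xp)
  y[(np + 1):(np + length(x))]
}

#' Preprocess an eye-position trace
#'
#' Position is low-pass filtered with a zero-phase FIR (default 60 Hz cutoff,
#' 30 taps) and then smoothed with a Savitzky-Golay filter (order 2 over a
#' 20 ms window, i.e. 7 samples at 350 Hz). Speed is the Euclidean norm of
#' the first-difference velocity; acceleration is the first difference of
#' speed, median-filtered over 3 samples. The output time grid is identical
#' to the input. The FIR cutoff is chosen so that the peak speed of a
#' minimum-jerk saccade of typical duration (35-70 ms) is preserved within
#' 1% of its analytic value `1.875 * A / D`.
#'
#' @param raw an `eye_trace` (see [simulate_eye_trace()]).
#' @param fir_cutoff FIR cutoff frequency, Hz.
#' @param fir_taps FIR order (number of taps - 1 is the filter order given to
#'   the design routine).
#' @param sg_window Savitzky-Golay window length in seconds.
#' @param sg_order Savitzky-Golay polynomial order.
#' @return the trace with filtered `x`, `y` and derived `speed` (deg/s) and
#'   `acceleration` (deg/s^2); `preprocessed` set to `TRUE`.
#' @export
preprocess_trace <- function(raw, fir_cutoff = 60, fir_taps = 30,
                             sg_window = 0.020, sg_order = 2) {
  fs <- raw$sampling_rate
  n_sg <- max(sg_order + 1, round(sg_window * fs))
  if (n_sg %% 2 == 0) n_sg <- n_sg + 1
  if (length(raw$time) < max(n_sg, fir_taps + 1)) {
    stop_invalid("trace shorter than the filter window")
  }
  b <- as.numeric(signal::fir1(fir_taps, fir_cutoff / (fs / 2)))
  b <- b / sum(b)  # exact unit DC gain so constants and ramps pass through
  x <- signal::sgolayfilt(zero_phase_fir(raw$x, b), p = sg_order, n = n_sg)
  y <- signal::sgolayfilt(zero_phase_fir(raw$y, b), p = sg_order, n = n_sg)
  vx <- c(0, diff(x)) * fs
  vy <- c(0, diff(y)) * fs
  speed <- sqrt(vx^2 + vy^2)
  acc <- stats::runmed(c(0, diff(speed)) * fs, k = 3)
  out <- raw
  out$x <- x; out$y <- y
  out$speed <- as.numeric(speed)
  out$acceleration <- as.numeric(acc)
  out$preprocessed <- TRUE
  out
}

#' Estimate fixation speed noise
#'
#' Pools preprocessed speed samples over the given fixation windows and
#' returns their standard deviation, the session-level noise figure that the
#' adaptive detection threshold (6 SD) is built on.
#'
#' @param trace a preprocessed `eye_trace`, or a list of them.
#' @param fixation_windows list of `c(start, end)` intervals in seconds (one
#'   list per trace when `trace` is a list).
#' @param min_total minimum pooled fixation time in seconds.
#' @return speed SD in deg/s.
#' @export
estimate_fixation_noise <- function(trace, fixation_windows,
                                    min_total = 0.5) {
  traces <- if (inherits(trace, "eye_trace")) list(trace) else trace
  wins <- if (inherits(trace, "eye_trace")) list(fixation_windows) else
    fixation_windows
  chunks <- list()
  total <- 0
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    if (!isTRUE(tr$preprocessed)) stop_invalid("traces must be preprocessed")
    for (w in wins[[i]]) {
      keep <- tr$time >= w[1] & tr$time < w[2]
      chunks[[length(chunks) + 1L]] <- tr$speed[keep]
      total <- total + max(0, w[2] - w[1])
    }
  }
  samples <- unlist(chunks, use.names = FALSE)
  if (total < min_total) {
    stop_invalid("insufficient fixation data (%.3f s < %.3f s)", total,
                 min_total)
  }
  out <- sd(samples)
  # Speed is non-negative, so its fixation-noise floor has a positive mean
  # (Rayleigh-like); downstream refinement thresholds need it.
  attr(out, "mean") <- mean(samples)
  out
}

refine_edge <- function(speed, i, low, step) {
  # walk from index i in direction `step` until speed drops below `low`
  n <- length(speed)
  while (i + step >= 1 && i + step <= n && speed[i + step] > low) {
    i <- i + step
  }
  j <- i + step
  if (j >= 1 && j <= n) j else i
}

#' Detect saccades with an adaptive velocity threshold
#'
#' Finds contiguous epochs where speed exceeds `threshold_mult * noise_sd`
#' (default 6 SD of the session's fixation noise), merges epochs separated by
#' less than `merge_gap`, discards epochs shorter than `min_duration`, and
#' refines each onset/offset outward to the nearest crossing of the low
#' threshold (`low_mult * noise_sd`). Peak velocity is refined by parabolic
#' interpolation around the sample maximum.
#'
#' @param trace a preprocessed `eye_trace`.
#' @param noise_sd fixation speed SD in deg/s (> 0); when it carries a
#'   `mean` attribute (as returned by [estimate_fixation_noise()]) the
#'   thresholds are offset by that fixation-speed mean, since speed is a
#'   non-negative norm whose noise floor does not sit at zero.
#' @param threshold_mult high-threshold multiplier (detection).
#' @param low_mult low-threshold multiplier (onset/offset refinement).
#' @param merge_gap epochs closer than this (s) are merged.
#' @param min_duration epochs shorter than this (s) are discarded.
#' @return data.frame of saccade events: `onset`, `offset`, `duration` (s),
#'   `amplitude` (deg, net displacement), `peak_velocity` (deg/s),
#'   `direction` (deg), and endpoint coordinates.
#' @export
detect_saccades <- function(trace, noise_sd, threshold_mult = 6,
                            low_mult = 1, merge_gap = 0.010,
                            min_duration = 0.010) {
  if (!isTRUE(trace$preprocessed)) stop_invalid("trace must be preprocessed")
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    stop_invalid("noise_sd must be > 0")
  }
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), amplitude = numeric(0),
                      peak_velocity = numeric(0), direction = numeric(0),
                      x_on = numeric(0), y_on = numeric(0),
                      x_off = numeric(0), y_off = numeric(0))
  noise_mean <- attr(noise_sd, "mean")
  if (is.null(noise_mean)) noise_mean <- 0
  hi <- noise_mean + threshold_mult * noise_sd
  lo <- noise_mean + low_mult * noise_sd
  above <- trace$speed > hi
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  fs <- trace$sampling_rate
  # merge segments separated by < merge_gap
  if (nrow(seg) > 1L) {
    merged <- seg[1, , drop = FALSE]
    for (k in 2:nrow(seg)) {
      gap <- (seg[k, 1] - merged[nrow(merged), 2] - 1) / fs
      if (gap < merge_gap) {
        merged[nrow(merged), 2] <- seg[k, 2]
      } else {
        merged <- rbind(merged, seg[k, ])
      }
    }
    seg <- merged
  }
  keep <- (seg[, 2] - seg[, 1] + 1) / fs >= min_duration
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg) == 0L) return(empty)
  ev <- lapply(seq_len(nrow(seg)), function(k) {
    i_on <- refine_edge(trace$speed, seg[k, 1], lo, -1L)
    i_off <- refine_edge(trace$speed, seg[k, 2], lo, +1L)
    sp <- trace$speed[seg[k, 1]:seg[k, 2]]
    im <- seg[k, 1] + which.max(sp) - 1L
    pk <- trace$speed[im]
    if (im > 1L && im < length(trace$speed)) {
      y1 <- trace$speed[im - 1L]; y2 <- pk; y3 <- trace$speed[im + 1L]
      den <- y1 - 2 * y2 + y3
      if (is.finite(den) && den < 0) pk <- y2 - (y3 - y1)^2 / (8 * den)
    }
    dx <- trace$x[i_off] - trace$x[i_on]
    dy <- trace$y[i_off] - trace$y[i_on]
    data.frame(onset = trace$time[i_on], offset = trace$time[i_off],
               duration = trace$time[i_off] - trace$time[i_on],
               amplitude = sqrt(dx^2 + dy^2), peak_velocity = pk,
               direction = atan2(dy, dx) * 180 / pi,
               x_on = trace$x[i_on], y_on = trace$y[i_on],
               x_off = trace$x[i_off], y_off = trace$y[i_off])
  })
  out <- do.call(rbind, ev)
  # refinement can merge adjacent epochs into identical events
  out[!duplicated(out$onset), , drop = FALSE]
}

#' Score a trial from its detected saccades
#'
#' Selects the first saccade launched at or after the go cue and classifies
#' the trial: `excluded` if the reaction time is below the anticipatory floor
#' (100 ms), `error` if no saccade occurs within the response window
#' (500 ms after the go cue), if the endpoint misses the required location,
#' or if gaze does not hold there; `correct` if the endpoint lands within
#' `win_deg` (6 deg) of the target (pro) or its mirror position (anti) and,
#' when the trace is supplied, gaze stays within that window for
#' `hold_s` (100 ms).
#'
#' @param trial one-row trial record.
#' @param events saccade events from [detect_saccades()] on this trial's
#'   trace.
#' @param trace optional preprocessed `eye_trace` used for the hold check.
#' @param win_deg spatial tolerance around the (anti-)target, degrees.
#' @param rt_floor anticipatory threshold, seconds.
#' @param max_rt response deadline after the go cue, seconds.
#' @param hold_s required post-saccadic hold, seconds.
#' @return the trial record with `outcome` set and detected kinematics
#'   (`t_sacc`, `rt`, `amplitude`, `peak_velocity`, `duration`) attached.
#' @export
score_trial <- function(trial, events, trace = NULL, win_deg = 6,
                        rt_floor = 0.100, max_rt = 0.500, hold_s = 0.100) {
  trial$t_sacc <- NA_real_; trial$rt <- NA_real_
  trial$amplitude <- NA_real_; trial$peak_velocity <- NA_real_
  trial$duration <- NA_real_
  post <- events[events$onset >= trial$t_go, , drop = FALSE]
  if (nrow(post) == 0L) {
    trial$outcome <- "error"   # no response
    return(trial)
  }
  ev <- post[which.min(post$onset), ]
  rt <- ev$onset - trial$t_go
  trial$t_sacc <- ev$onset
  trial$rt <- rt
  trial$amplitude <- ev$amplitude
  trial$peak_velocity <- ev$peak_velocity
  trial$duration <- ev$duration
  if (rt < rt_floor) {
    trial$outcome <- "excluded"  # anticipatory
    return(trial)
  }
  if (rt > max_rt) {
    trial$outcome <- "error"     # timeout
    return(trial)
  }
  theta <- trial$direction * 45 * pi / 180
  amp <- trial$target_amplitude
  sgn <- if (trial$condition == "pro") 1 else -1
  gx <- sgn * amp * cos(theta)
  gy <- sgn * amp * sin(theta)
  miss <- sqrt((ev$x_off - gx)^2 + (ev$y_off - gy)^2)
  ok <- is.finite(miss) && miss <= win_deg
  if (ok && !is.null(trace)) {
    keep <- trace$time >= ev$offset & trace$time < ev$offset + hold_s
    if (any(keep)) {
      d <- sqrt((trace$x[keep] - gx)^2 + (trace$y[keep] - gy)^2)
      ok <- all(d <= win_deg)
    }
  }
  trial$outcome <- if (ok) "correct" else "error"
  trial
}

#' Run the full detection chain over a session
#'
#' Preprocesses every eye trace, estimates the session fixation noise from
#' the pooled instruction-period windows, detects saccades on every trial,
#' and scores each trial. The scored trial table is propagated to every cell
#' recording in the session.
#'
#' @param session a `pc_session` from [generate_population()], or any list
#'   with `trials` and `eye`.
#' @param ... passed on to [detect_saccades()].
#' @return the session with scored `trials`, a `saccades` data.frame of all
#'   detected events (with `trial_id`), and `noise_sd` recorded.
#' @export
detect_session <- function(session, ...) {
  trials <- session$trials
  for (col in c("t_sacc", "rt", "amplitude", "peak_velocity", "duration")) {
    trials[[col]] <- NA_real_
  }
  pre <- lapply(session$eye, preprocess_trace)
  wins <- lapply(seq_len(nrow(trials)), function(k) {
    list(c(trials$t_fix_on[k], trials$t_target_on[k]))
  })
  noise_sd <- estimate_fixation_noise(pre, wins)
  all_ev <- list()
  for (k in seq_len(nrow(trials))) {
    ev <- detect_saccades(pre[[k]], noise_sd, ...)
    trials[k, ] <- score_trial(trials[k, ], ev, trace = pre[[k]])
    if (nrow(ev) > 0L) {
      ev$trial_id <- trials$trial_id[k]
      all_ev[[length(all_ev) + 1L]] <- ev
    }
  }
  session$trials <- trials
  session$saccades <- if (length(all_ev)) do.call(rbind, all_ev) else NULL
  session$noise_sd <- noise_sd
  session$cells <- lapply(session$cells, function(cell) {
    cell$trials <- trials
    cell
  })
  session
}
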