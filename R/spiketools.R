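# Spike-train containers, event alignment, spike density functions, and
# Purkinje cell identification via the post-complex-spike pause.

#' Compute a Gaussian-kernel spike density function
#'
#' The SDF is the sum of unit-mass Gaussians of SD `sigma` centred on the
#' spike times, evaluated on a 1 ms grid over `window`. No edge
#' renormalisation is applied: a spike's kernel mass falling outside the
#' window is simply lost, so the integral of the SDF equals the spike count
#' only when the window extends well past all spikes (>= 5 sigma for 1e-6
#' relative accuracy).
#'
#' @param spikes numeric spike times, seconds.
#' @param window `c(start, end)` evaluation interval, seconds.
#' @param sigma kernel SD in seconds (50 ms for simple spikes, 25 ms for the
#'   sparser complex spikes are the conventional choices here).
#' @param dt grid step, seconds.
#' @return an object of class `sdf`: list with `time`, `rate` (spikes/s),
#'   `sigma`, `n_spikes`.
#' @export
compute_sdf <- function(spikes, window, sigma = 0.050, dt = 0.001) {
  if (sigma <= 0) stop_invalid("sigma must be > 0")
  if (length(window) != 2L || window[2] <= window[1]) {
    stop_invalid("window must be a non-empty interval")
  }
  grid <- seq(window[1], window[2], by = dt)
  rate <- numeric(length(grid))
  if (length(spikes) > 0L) {
    half <- ceiling(6 * sigma / dt)
    for (s in spikes) {
      ic <- round((s - window[1]) / dt) + 1
      i0 <- max(1, ic - half); i1 <- min(length(grid), ic + half)
      if (i1 < 1 || i0 > length(grid)) next
      rate[i0:i1] <- rate[i0:i1] + dnorm(grid[i0:i1], s, sigma)
    }
  }
  structure(list(time = grid, rate = rate, sigma = sigma,
                 n_spikes = length(spikes)),
            class = "sdf")
}

event_column <- function(event) {
  cols <- c(trial_onset = "t_fix_on", target_on = "t_target_on",
            instruction_offset = "t_target_on", go_cue = "t_go",
            saccade_onset = "t_sacc")
  if (!event %in% names(cols)) {
    stop_invalid("unknown alignment event '%s'", event)
  }
  cols[[event]]
}

#' Align spikes to a trial event
#'
#' Re-expresses spike times relative to a per-trial event and restricts them
#' to a half-open window `[a, b)`. Trials lacking the event (e.g. no detected
#' saccade) are dropped; their count is recorded in the `n_dropped`
#' attribute.
#'
#' @param cell a `cell_recording` (or any list with `ss_times`, `cs_times`,
#'   `trials`).
#' @param event one of `"trial_onset"` (fixation onset), `"target_on"` /
#'   `"instruction_offset"`, `"go_cue"`, `"saccade_onset"`.
#' @param window `c(a, b)` relative window, seconds.
#' @param spike_type `"ss"` or `"cs"`.
#' @param outcomes trial outcomes to keep (default correct trials only).
#' @param condition optional `"pro"`/`"anti"` filter.
#' @param direction optional direction filter (0-7).
#' @return list of per-trial numeric vectors of relative spike times; trial
#'   ids as names; attribute `n_dropped`.
#' @export
align <- function(cell, event, window, spike_type = c("ss", "cs"),
                  outcomes = "correct", condition = NULL, direction = NULL) {
  spike_type <- match.arg(spike_type)
  col <- event_column(event)
  trials <- cell$trials
  if (!col %in% names(trials)) {
    stop_invalid("trials lack event column '%s'; score the session first",
                 col)
  }
  keep <- trials$outcome %in% outcomes
  if (!is.null(condition)) keep <- keep & trials$condition == condition
  if (!is.null(direction)) keep <- keep & trials$direction == direction
  trials <- trials[keep, , drop = FALSE]
  have <- !is.na(trials[[col]])
  n_dropped <- sum(!have)
  trials <- trials[have, , drop = FALSE]
  spikes <- if (spike_type == "ss") cell$ss_times else cell$cs_times
  out <- lapply(seq_len(nrow(trials)), function(k) {
    e <- trials[[col]][k]
    spikes_in_window(spikes, e + window[1], e + window[2], origin = e)
  })
  names(out) <- trials$trial_id
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Trial-averaged spike density function
#'
#' Pools event-aligned spikes over trials and returns their SDF divided by
#' the number of trials. Spikes are collected from a window padded by
#' `4 * sigma` on each side so that the estimate within `window` carries no
#' edge bias, then evaluated on `window`.
#'
#' @inheritParams align
#' @param sigma kernel SD, seconds.
#' @return an `sdf` with an extra field `n_trials`.
#' @export
trial_sdf <- function(cell, event, window, sigma = 0.050,
                      spike_type = c("ss", "cs"), outcomes = "correct",
                      condition = NULL, direction = NULL) {
  spike_type <- match.arg(spike_type)
  pad <- 4 * sigma
  al <- align(cell, event, c(window[1] - pad, window[2] + pad),
              spike_type = spike_type, outcomes = outcomes,
              condition = condition, direction = direction)
  n <- length(al)
  if (n == 0L) stop_invalid("no trials available for trial_sdf")
  s <- compute_sdf(sort(unlist(al, use.names = FALSE)), window, sigma)
  s$rate <- s$rate / n
  s$n_trials <- n
  s
}

#' Verify the post-complex-spike pause in simple-spike firing
#'
#' Purkinje cells are identified by a short pause in SS firing after each CS
#' (the climbing-fibre pause). This computes the CS-triggered SS
#' cross-correlogram (1 ms bins, lags 0-50 ms) over the first
#' `check_duration` seconds of the recording and reports `TRUE` when a run
#' of at least `min_run_ms` consecutive bins falls below `frac` times the
#' pre-CS baseline rate (lags -50..0 ms). With fewer than `min_cs` complex
#' spikes the result is indeterminate (`NA`).
#'
#' @param cell a `cell_recording`.
#' @param check_duration seconds of recording examined from its start.
#' @param min_cs minimum number of CS required for a determinate answer.
#' @param frac pause criterion as a fraction of the baseline rate.
#' @param min_run_ms minimum consecutive sub-threshold run, ms.
#' @return list with `is_pc` (`TRUE`/`FALSE`/`NA`), `pause_ms` (longest
#'   sub-threshold run), `n_cs`, and `baseline_rate` (spikes/s).
#' @export
verify_cs_pause <- function(cell, check_duration = 120, min_cs = 10,
                            frac = 0.5, min_run_ms = 8) {
  cs <- cell$cs_times[cell$cs_times <= check_duration]
  if (length(cs) < min_cs) {
    return(list(is_pc = NA, pause_ms = NA_real_, n_cs = length(cs),
                baseline_rate = NA_real_))
  }
  lags <- seq(-0.050, 0.050, by = 0.001)
  counts <- numeric(length(lags) - 1)
  ss <- cell$ss_times
  for (c0 in cs) {
    rel <- spikes_in_window(ss, c0 - 0.050, c0 + 0.050, origin = c0)
    if (length(rel)) {
      counts <- counts + tabulate(findInterval(rel, lags), length(counts))
    }
  }
  rate <- counts / (length(cs) * 0.001)
  mid <- seq(-0.0495, 0.0495, by = 0.001)
  base <- mean(rate[mid < 0])
  post <- rate[mid > 0]
  below <- post < frac * base
  runs <- rle(below)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0
  list(is_pc = longest >= min_run_ms, pause_ms = as.numeric(longest),
       n_cs = length(cs), baseline_rate = base)
}
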