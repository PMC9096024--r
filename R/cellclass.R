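# Cell inclusion and classification: saccade-related test,
# facilitation/suppression per epoch, ramping, pro-vs-anti difference.

correct_trials <- function(cell) {
  cell$trials[cell$trials$outcome == "correct", , drop = FALSE]
}

# Per-trial firing rate (spikes/s) in half-open windows [t0 + a, t0 + b).
trial_rates <- function(spikes, t0, a, b) {
  count_in_window(spikes, t0 + a, t0 + b) / (b - a)
}

#' Trial-count inclusion rule
#'
#' A cell enters the statistical analyses only when it has at least
#' `min_trials` correct trials for every combination of the 8 directions and
#' 2 conditions.
#'
#' @param cell a `cell_recording` with scored trials.
#' @param min_trials minimum correct trials per (direction, condition).
#' @return logical.
#' @export
check_inclusion <- function(cell, min_trials = 5) {
  tr <- correct_trials(cell)
  tab <- table(factor(tr$direction, levels = 0:7),
               factor(tr$condition, levels = c("pro", "anti")))
  all(tab >= min_trials)
}

#' Baseline simple-spike rate
#'
#' Mean firing rate in the intertrial baseline window 400 to 50 ms before
#' fixation onset, averaged over correct trials.
#'
#' @param cell a `cell_recording`.
#' @param spike_type `"ss"` or `"cs"`.
#' @return spikes/s.
#' @export
baseline_rate <- function(cell, spike_type = c("ss", "cs")) {
  spike_type <- match.arg(spike_type)
  spikes <- if (spike_type == "ss") cell$ss_times else cell$cs_times
  tr <- correct_trials(cell)
  mean(trial_rates(spikes, tr$t_fix_on, -0.400, -0.050))
}

#' Test whether a cell is saccade-related
#'
#' For each of the 8 directions, compares per-trial SS rates in the
#' intertrial baseline window (400-50 ms before fixation onset) against the
#' 150 ms window after saccade onset with an unpaired Wilcoxon rank-sum test
#' (window counts scaled to rates to offset the unequal window lengths). The
#' cell is saccade-related when any direction is significant at `alpha`
#' (uncorrected). Directions without detected saccade onsets are skipped.
#'
#' @param cell a `cell_recording` with scored trials.
#' @param alpha significance level per direction.
#' @return list with `related` (logical) and `p` (length-8 vector,
#'   `NA` for skipped directions).
#' @export
classify_saccade_related <- function(cell, alpha = 0.05) {
  tr <- correct_trials(cell)
  p <- rep(NA_real_, 8)
  for (d in 0:7) {
    td <- tr[tr$direction == d & !is.na(tr$t_sacc), , drop = FALSE]
    if (nrow(td) < 2L) next
    base <- trial_rates(cell$ss_times, td$t_fix_on, -0.400, -0.050)
    sacc <- trial_rates(cell$ss_times, td$t_sacc, 0, 0.150)
    p[d + 1] <- suppressWarnings(wilcox.test(sacc, base)$p.value)
  }
  list(related = any(p < alpha, na.rm = TRUE), p = p)
}

#' Classify an epoch response as facilitation, suppression, or none
#'
#' Paired Wilcoxon signed-rank test on per-trial mean rates between a
#' pre-epoch and an epoch window. For the instruction epoch: 400 ms before
#' instruction (fixation) onset vs. the last 300 ms of the instruction
#' period. For the saccade epoch: 150 ms before saccade onset vs. the 150 ms
#' after it. A significant increase is `"facilitation"`, a significant
#' decrease `"suppression"`, otherwise `"none"`. With fewer than
#' `min_pairs` paired trials the result is indeterminate (`NA`).
#'
#' @param cell a `cell_recording` with scored trials.
#' @param epoch `"instruction"` or `"saccade"`.
#' @param condition `"pro"` or `"anti"`.
#' @param alpha significance level.
#' @param min_pairs minimum paired trials.
#' @return `"facilitation"`, `"suppression"`, `"none"`, or `NA`.
#' @export
classify_epoch_response <- function(cell, epoch = c("instruction", "saccade"),
                                    condition = c("pro", "anti"),
                                    alpha = 0.05, min_pairs = 5) {
  epoch <- match.arg(epoch)
  condition <- match.arg(condition)
  tr <- correct_trials(cell)
  tr <- tr[tr$condition == condition, , drop = FALSE]
  if (epoch == "instruction") {
    pre <- trial_rates(cell$ss_times, tr$t_fix_on, -0.400, 0)
    post <- trial_rates(cell$ss_times, tr$t_target_on, -0.300, 0)
  } else {
    tr <- tr[!is.na(tr$t_sacc), , drop = FALSE]
    pre <- trial_rates(cell$ss_times, tr$t_sacc, -0.150, 0)
    post <- trial_rates(cell$ss_times, tr$t_sacc, 0, 0.150)
  }
  if (length(pre) < min_pairs) return(NA_character_)
  d <- post - pre
  if (all(d == 0)) return("none")
  p <- suppressWarnings(wilcox.test(post, pre, paired = TRUE)$p.value)
  if (is.na(p) || p >= alpha) return("none")
  if (mean(d) > 0) "facilitation" else "suppression"
}

#' Classify ramping activity during the late instruction period
#'
#' Fits ordinary least squares to the trial-averaged firing rate over the
#' last 300 ms of the instruction period (aligned to target onset) and calls
#' the cell ramping when R^2 exceeds `r2_threshold` (0.75). The rate is
#' averaged in `bin` s bins (default 30 ms, 10 points): independent bin
#' noise keeps the null R^2 calibrated, which heavily smoothed density
#' estimates would not (smooth noise masquerades as a linear trend).
#'
#' @param cell a `cell_recording` with scored trials.
#' @param condition `"pro"` or `"anti"`.
#' @param r2_threshold R^2 above which the cell is called ramping.
#' @param bin bin width in seconds.
#' @return list with `ramping` (logical), `slope` (spks/s per s), and
#'   `r_squared`.
#' @export
classify_ramping <- function(cell, condition = c("pro", "anti"),
                             r2_threshold = 0.75, bin = 0.030) {
  condition <- match.arg(condition)
  tr <- correct_trials(cell)
  tr <- tr[tr$condition == condition, , drop = FALSE]
  edges <- seq(-0.300, 0, by = bin)
  mids <- edges[-1] - bin / 2
  n <- nrow(tr)
  if (n == 0L) return(list(ramping = FALSE, slope = NA_real_,
                           r_squared = NA_real_))
  rate <- sapply(seq_along(mids), function(j) {
    mean(count_in_window(cell$ss_times, tr$t_target_on + edges[j],
                         tr$t_target_on + edges[j + 1])) / bin
  })
  if (var(rate) == 0) {
    return(list(ramping = FALSE, slope = 0, r_squared = NA_real_))
  }
  fit <- lm(rate ~ mids)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(ramping = r2 > r2_threshold, slope = unname(coef(fit)[2]),
       r_squared = r2)
}

#' Pro- vs. anti-saccade condition difference (Kolmogorov-Smirnov)
#'
#' Two-sample K-S test on per-trial spike counts in the 150 ms window after
#' saccade onset, prosaccade vs. antisaccade correct trials.
#'
#' @param cell a `cell_recording` with scored trials.
#' @return the K-S p-value.
#' @export
test_condition_difference <- function(cell) {
  tr <- correct_trials(cell)
  tr <- tr[!is.na(tr$t_sacc), , drop = FALSE]
  cnt <- count_in_window(cell$ss_times, tr$t_sacc, tr$t_sacc + 0.150)
  pro <- cnt[tr$condition == "pro"]
  anti <- cnt[tr$condition == "anti"]
  suppressWarnings(ks.test(pro, anti)$p.value)
}

#' Full classification of one cell
#'
#' Runs the inclusion rule, the saccade-related test, per-epoch and
#' per-condition facilitation/suppression classification, ramping, and the
#' pro/anti condition test, returning one row per condition.
#'
#' @param cell a `cell_recording` with scored trials.
#' @return data.frame with columns `cell_id`, `region`, `condition`,
#'   `included`, `saccade_related`, `min_saccade_p`, `instruction_class`,
#'   `saccade_class`, `ramping`, `ramp_slope`, `ramp_r2`,
#'   `condition_diff_p`, `baseline_rate`.
#' @export
classify_cell <- function(cell) {
  inc <- check_inclusion(cell)
  sr <- classify_saccade_related(cell)
  ksp <- test_condition_difference(cell)
  base <- baseline_rate(cell)
  do.call(rbind, lapply(c("pro", "anti"), function(cond) {
    ramp <- classify_ramping(cell, cond)
    data.frame(
      cell_id = cell$cell_id, region = cell$region, condition = cond,
      included = inc, saccade_related = sr$related,
      min_saccade_p = suppressWarnings(min(sr$p, na.rm = TRUE)),
      instruction_class = classify_epoch_response(cell, "instruction", cond),
      saccade_class = classify_epoch_response(cell, "saccade", cond),
      ramping = ramp$ramping, ramp_slope = ramp$slope,
      ramp_r2 = ramp$r_squared,
      condition_diff_p = ksp, baseline_rate = base,
      stringsAsFactors = FALSE
    )
  }))
}

#' Classify every cell of a session
#'
#' @param session a scored `pc_session`.
#' @return data.frame, two rows (pro/anti) per cell; see [classify_cell()].
#' @export
classify_population <- function(session) {
  do.call(rbind, lapply(session$cells, classify_cell))
}
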