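# Population-level simple-spike metrics: modulation ratio, response latency,
# kinematic regression with corrected firing, group comparisons.

#' Pro/anti modulation ratio
#'
#' Ratio of the mean saccade-window (150 ms after saccade onset) SS rate on
#' prosaccade trials to that on antisaccade trials. 1 means identical
#' responses; > 1 means stronger prosaccade activity.
#'
#' @param cell a `cell_recording` with scored trials.
#' @param window saccade response window `c(a, b)` relative to saccade
#'   onset, seconds.
#' @return the ratio, or `NA` (with a warning) when the antisaccade response
#'   is not positive.
#' @export
modulation_ratio <- function(cell, window = c(0, 0.150)) {
  tr <- correct_trials(cell)
  tr <- tr[!is.na(tr$t_sacc), , drop = FALSE]
  rate <- function(cond) {
    td <- tr[tr$condition == cond, , drop = FALSE]
    mean(trial_rates(cell$ss_times, td$t_sacc, window[1], window[2]))
  }
  pro <- rate("pro"); anti <- rate("anti")
  if (!is.finite(anti) || anti <= 0) {
    warning("antisaccade response not positive; modulation ratio undefined")
    return(NA_real_)
  }
  pro / anti
}

#' Response latency of the post-saccadic peak or trough
#'
#' Time from saccade onset to the maximum (facilitation cells) or minimum
#' (suppression cells) of the trial-averaged SS density function within
#' `(0, search_end]` s after onset. Pro- and anti-saccade trials are pooled
#' unless `condition` is given.
#'
#' @param cell a `cell_recording` with scored trials.
#' @param group `"facilitation"` (peak) or `"suppression"` (trough).
#' @param condition optional `"pro"`/`"anti"` restriction.
#' @param search_end end of the search window, seconds after onset.
#' @param sigma SDF kernel SD, seconds.
#' @param min_range SDFs with peak-to-trough range below this (spks/s) are
#'   treated as flat and return `NA`.
#' @return latency in seconds; attribute `at_boundary` is `TRUE` when the
#'   extremum sits on the window edge (degenerate monotone profile).
#' @export
response_latency <- function(cell, group = c("facilitation", "suppression"),
                             condition = NULL, search_end = 0.300,
                             sigma = 0.050, min_range = 1) {
  group <- match.arg(group)
  s <- trial_sdf(cell, "saccade_onset", c(0, search_end), sigma = sigma,
                 condition = condition)
  keep <- s$time > 0
  tt <- s$time[keep]; rr <- s$rate[keep]
  if (diff(range(rr)) < min_range) return(NA_real_)
  i <- if (group == "facilitation") which.max(rr) else which.min(rr)
  out <- tt[i]
  attr(out, "at_boundary") <- i == 1L || i == length(rr)
  out
}

#' Regression of firing rate on saccade kinematics
#'
#' For each cell, regresses the per-trial saccade-window SS rate on a
#' detected kinematic parameter (amplitude or peak speed): Pearson
#' correlation with its p-value, OLS slope beta, and the corrected per-trial
#' firing rates `rate / beta` (undefined when beta is indistinguishable from
#' zero).
#'
#' @param cells list of `cell_recording`s with scored trials.
#' @param kinematic `"amplitude"` or `"peak_speed"`.
#' @param window SS response window relative to saccade onset.
#' @param beta_tol slopes with `|beta|` below this are treated as zero.
#' @return list with `summary` (data.frame: `cell_id`, `r`, `p`, `beta`,
#'   `n_trials`) and `corrected` (named list of per-trial corrected rates,
#'   `NULL` where undefined).
#' @export
kinematic_regression <- function(cells, kinematic = c("amplitude",
                                                      "peak_speed"),
                                 window = c(0, 0.150), beta_tol = 1e-8) {
  kinematic <- match.arg(kinematic)
  col <- if (kinematic == "amplitude") "amplitude" else "peak_velocity"
  rows <- list(); corrected <- list()
  for (cell in cells) {
    tr <- correct_trials(cell)
    tr <- tr[!is.na(tr$t_sacc) & !is.na(tr[[col]]), , drop = FALSE]
    rate <- trial_rates(cell$ss_times, tr$t_sacc, window[1], window[2])
    x <- tr[[col]]
    if (length(rate) < 3L || var(rate) == 0 || var(x) == 0) {
      stop_invalid("cell %s: degenerate rate or kinematic variance",
                   cell$cell_id)
    }
    ct <- cor.test(x, rate)
    beta <- unname(coef(lm(rate ~ x))[2])
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cell$cell_id, r = unname(ct$estimate), p = ct$p.value,
      beta = beta, n_trials = length(rate), stringsAsFactors = FALSE)
    corrected[[cell$cell_id]] <- if (abs(beta) > beta_tol) rate / beta else
      NULL
  }
  list(summary = do.call(rbind, rows), corrected = corrected)
}

cohen_d_pooled <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Group comparison with effect size
#'
#' Runs the requested two-group test and, for two-sample comparisons,
#' reports pooled-SD Cohen's d.
#'
#' @param a,b numeric vectors, or for `"chi2_proportions"` a 2x2 count
#'   matrix in `a` (`b` ignored).
#' @param test `"ranksum"` (Wilcoxon rank-sum), `"signed_rank"` (paired
#'   Wilcoxon), `"ks"` (two-sample Kolmogorov-Smirnov), or
#'   `"chi2_proportions"` (uncorrected chi-squared on a 2x2 table).
#' @return list with `statistic`, `p`, `cohen_d` (`NA` where not defined).
#' @export
compare_groups <- function(a, b = NULL,
                           test = c("ranksum", "signed_rank", "ks",
                                    "chi2_proportions")) {
  test <- match.arg(test)
  if (test == "chi2_proportions") {
    m <- as.matrix(a)
    if (!all(dim(m) == c(2L, 2L))) stop_invalid("need a 2x2 count table")
    h <- suppressWarnings(chisq.test(m, correct = FALSE))
    return(list(statistic = unname(h$statistic), p = h$p.value,
                cohen_d = NA_real_))
  }
  if (length(a) < 3L || length(b) < 3L) {
    stop_invalid("each group needs at least 3 values")
  }
  if (test == "signed_rank" && length(a) != length(b)) {
    stop_invalid("paired test requires equal lengths")
  }
  h <- switch(test,
    ranksum = suppressWarnings(wilcox.test(a, b)),
    signed_rank = suppressWarnings(wilcox.test(a, b, paired = TRUE)),
    ks = suppressWarnings(ks.test(a, b)))
  d <- if (test == "ks" || test == "ranksum") cohen_d_pooled(a, b)
       else cohen_d_pooled(a, b)
  list(statistic = unname(h$statistic), p = h$p.value, cohen_d = d)
}

#' Baseline-normalised trial-averaged SDF
#'
#' z-scores a cell's event-aligned trial-averaged SDF against the mean and
#' SD of its own intertrial baseline SDF (window 400-50 ms before fixation
#' onset), the normalisation used for population-average response traces.
#'
#' @inheritParams trial_sdf
#' @return an `sdf` whose `rate` is in baseline SD units.
#' @export
normalized_sdf <- function(cell, event = "saccade_onset",
                           window = c(-0.2, 0.3), sigma = 0.050,
                           condition = NULL) {
  base <- trial_sdf(cell, "trial_onset", c(-0.400, -0.050), sigma = sigma,
                    condition = condition)
  s <- trial_sdf(cell, event, window, sigma = sigma, condition = condition)
  mu <- mean(base$rate)
  sdv <- sd(base$rate)
  if (sdv == 0) sdv <- 1
  s$rate <- (s$rate - mu) / sdv
  s
}
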