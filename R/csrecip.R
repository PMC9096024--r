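# Complex-spike inclusion, epoch modulation, and CS-SS reciprocity with its
# regression and Cook's-distance outlier rule.

#' Complex-spike inclusion rule
#'
#' A cell enters the CS analyses when its session-wide CS rate is at least
#' `min_rate` Hz (boundary inclusive) and it has at least `min_trials`
#' correct trials per (direction, condition).
#'
#' @param cell a `cell_recording` with scored trials.
#' @param min_rate minimum session-wide CS rate, Hz.
#' @param min_trials minimum correct trials per (direction, condition).
#' @return logical.
#' @export
cs_inclusion <- function(cell, min_rate = 0.5, min_trials = 5) {
  dur <- if (!is.null(cell$duration)) cell$duration else
    max(cell$trials$t_trial_end)
  rate <- length(cell$cs_times) / dur
  rate >= min_rate && check_inclusion(cell, min_trials)
}

cs_epoch_window <- function(epoch) {
  switch(epoch,
         instruction = list(event = "trial_onset", window = c(0.050, 0.350)),
         saccade = list(event = "saccade_onset", window = c(-0.150, 0.150)),
         stop_invalid("unknown epoch '%s'", epoch))
}

# Trial-averaged CS SDF over the intertrial baseline. The mean comes from
# the 500 ms immediately before fixation onset; the SD is estimated over the
# full intertrial stretch (default 1.45 s) because 500 ms of a ~1 Hz CS
# density holds too few independent kernel widths for a stable SD, which
# would inflate the +/-3 SD false-positive rate.
cs_baseline_sdf <- function(cell, sigma, condition = NULL,
                            sd_window = c(-1.45, 0)) {
  s <- trial_sdf(cell, "trial_onset", c(-0.500, 0), sigma = sigma,
                 spike_type = "cs", condition = condition)
  s_long <- trial_sdf(cell, "trial_onset", sd_window, sigma = sigma,
                      spike_type = "cs", condition = condition)
  list(mean = mean(s$rate), sd = sd(s_long$rate))
}

#' Complex-spike epoch modulation
#'
#' Compares the trial-averaged CS density function in the epoch window
#' (instruction: 50-350 ms after instruction onset; saccade: +/-150 ms
#' around saccade onset) against the mean +/- 3 SD band of the intertrial
#' baseline CS density (500 ms before fixation onset). The modulation is
#' `"up"` or `"down"` by the sign of the first exceedance, `"none"`
#' otherwise.
#'
#' @param cell a `cell_recording` passing [cs_inclusion()].
#' @param epoch `"instruction"` or `"saccade"`.
#' @param condition optional `"pro"`/`"anti"` restriction (default pools).
#' @param sigma CS kernel SD, seconds (narrower than for SS because CS are
#'   sparse).
#' @param n_sd width of the significance band in baseline SDs.
#' @return `"none"`, `"up"`, or `"down"`.
#' @export
cs_epoch_modulation <- function(cell, epoch = c("instruction", "saccade"),
                                condition = NULL, sigma = 0.025, n_sd = 3) {
  epoch <- match.arg(epoch)
  w <- cs_epoch_window(epoch)
  base <- cs_baseline_sdf(cell, sigma, condition)
  if (!is.finite(base$sd)) stop_invalid("no intertrial baseline available")
  s <- trial_sdf(cell, w$event, w$window, sigma = sigma, spike_type = "cs",
                 condition = condition)
  dev <- s$rate - base$mean
  exc <- which(abs(dev) > n_sd * base$sd)
  if (length(exc) == 0L) return("none")
  if (dev[exc[1]] > 0) "up" else "down"
}

#' CS-SS reciprocity for one cell, epoch, and condition
#'
#' Finds the extremal deviation of the trial-averaged CS density from its
#' intertrial baseline within the epoch window (`delta_cs`, sign retained),
#' then the extremal deviation of the SS density from its own baseline
#' within +/-150 ms of the CS-peak time (`delta_ss`), and reports their
#' product. A negative product marks reciprocal (opposite-signed)
#' modulation.
#'
#' @param cell a `cell_recording` passing [cs_inclusion()].
#' @param epoch `"instruction"` or `"saccade"`.
#' @param condition `"pro"` or `"anti"`.
#' @param sigma_cs,sigma_ss kernel SDs for the CS and SS densities, seconds.
#' @return list with `delta_cs` (Hz), `delta_ss` (spks/s), `product`
#'   (Hz * spks/s), and `t_cs_peak` (s, relative to the epoch's alignment
#'   event).
#' @export
reciprocity <- function(cell, epoch = c("instruction", "saccade"),
                        condition = c("pro", "anti"),
                        sigma_cs = 0.025, sigma_ss = 0.050) {
  epoch <- match.arg(epoch)
  condition <- match.arg(condition)
  w <- cs_epoch_window(epoch)
  cs_base <- cs_baseline_sdf(cell, sigma_cs, condition)
  s_cs <- trial_sdf(cell, w$event, w$window, sigma = sigma_cs,
                    spike_type = "cs", condition = condition)
  dev_cs <- s_cs$rate - cs_base$mean
  i <- which.max(abs(dev_cs))
  delta_cs <- dev_cs[i]
  t_peak <- s_cs$time[i]
  ss_base <- trial_sdf(cell, "trial_onset", c(-0.500, 0), sigma = sigma_ss,
                       condition = condition)
  s_ss <- trial_sdf(cell, w$event, c(t_peak - 0.150, t_peak + 0.150),
                    sigma = sigma_ss, condition = condition)
  dev_ss <- s_ss$rate - mean(ss_base$rate)
  delta_ss <- dev_ss[which.max(abs(dev_ss))]
  list(delta_cs = delta_cs, delta_ss = delta_ss,
       product = delta_cs * delta_ss, t_cs_peak = t_peak)
}

#' Reciprocity table for a set of cells
#'
#' @param cells list of `cell_recording`s (cells failing [cs_inclusion()]
#'   are skipped).
#' @param ... passed to [reciprocity()].
#' @return data.frame with one row per cell x epoch x condition.
#' @export
reciprocity_table <- function(cells, ...) {
  rows <- list()
  for (cell in cells) {
    if (!cs_inclusion(cell)) next
    for (epoch in c("instruction", "saccade")) {
      for (cond in c("pro", "anti")) {
        r <- reciprocity(cell, epoch, cond, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = cell$cell_id, region = cell$region, epoch = epoch,
          condition = cond, delta_cs = r$delta_cs, delta_ss = r$delta_ss,
          product = r$product, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Regression of saccade-epoch on instruction-epoch reciprocity
#'
#' Ordinary least squares of each cell's saccade-period reciprocity product
#' on its instruction-period product. Points whose Cook's distance exceeds
#' three times the mean Cook's distance are removed once and the model is
#' refit; the exclusion pass is deliberately not iterated.
#'
#' @param recip data.frame from [reciprocity_table()], or any frame with
#'   columns `cell_id`, `epoch`, `condition`, `product`.
#' @param region optional region filter (requires a `region` column).
#' @param condition `"pro"` or `"anti"`.
#' @param min_cells minimum number of cells with both epoch products.
#' @return list with `slope`, `intercept`, `r_squared`, `excluded`
#'   (cell ids), `n` (cells in the final fit), and the final `fit`.
#' @export
reciprocity_regression <- function(recip, region = NULL,
                                   condition = c("pro", "anti"),
                                   min_cells = 5) {
  condition <- match.arg(condition)
  df <- recip[recip$condition == condition, , drop = FALSE]
  if (!is.null(region)) df <- df[df$region == region, , drop = FALSE]
  instr <- df[df$epoch == "instruction", c("cell_id", "product")]
  sacc <- df[df$epoch == "saccade", c("cell_id", "product")]
  m <- merge(instr, sacc, by = "cell_id", suffixes = c("_instr", "_sacc"))
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < min_cells) {
    stop_invalid("need >= %d cells with both epoch products (have %d)",
                 min_cells, nrow(m))
  }
  fit <- lm(product_sacc ~ product_instr, data = m)
  cd <- cooks.distance(fit)
  out <- cd > 3 * mean(cd)
  excluded <- m$cell_id[out]
  if (any(out)) {
    m2 <- m[!out, , drop = FALSE]
    fit <- lm(product_sacc ~ product_instr, data = m2)
  } else {
    m2 <- m
  }
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       excluded = excluded, n = nrow(m2), fit = fit)
}
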