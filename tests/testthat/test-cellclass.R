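# Inclusion, saccade-related, epoch, ramping, and condition-difference rules.

# Homogeneous-Poisson "flat" cell over a manual trial table (no generator).
flat_cell <- function(trials, rate = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_end <- max(trials$t_trial_end)
  n <- rpois(1, rate * t_end)
  make_manual_cell(sort(runif(n, 0, t_end)), numeric(0), trials)
}

test_that("the 5-trial inclusion rule is a strict per-cell boundary", {
  trials <- make_manual_trials(80)   # 5 per (direction, condition)
  cell <- make_manual_cell(runif(100, 0, max(trials$t_trial_end)),
                           numeric(0), trials)
  expect_true(check_inclusion(cell))
  trials2 <- trials
  trials2$outcome[which(trials2$direction == 3 &
                          trials2$condition == "anti")[1]] <- "error"
  cell2 <- make_manual_cell(cell$ss_times, numeric(0), trials2)
  expect_false(check_inclusion(cell2))
})

test_that("flat cells trigger the saccade-related rule at the uncorrected rate", {
  # 8 uncorrected tests at alpha = 0.05: expected family-wise false-positive
  # rate 1 - 0.95^8 ~ 0.34
  trials <- make_manual_trials(80)
  set.seed(101)
  hits <- vapply(seq_len(400), function(i) {
    classify_saccade_related(flat_cell(trials))$related
  }, logical(1))
  expect_gte(mean(hits), 0.25)
  expect_lte(mean(hits), 0.45)
})

test_that("strong saccade transients are reliably saccade-related", {
  cfg <- cell_config(baseline_rate_ss = 60, saccade_profile = "facilitation",
                     saccade_gain = 30, saccade_latency = 0.05,
                     cs_baseline = 0)
  for (seed in 1:5) {
    cell <- make_cell(cfg, n_blocks = 5, seed = seed)  # 10 per (dir, cond)
    expect_true(classify_saccade_related(cell)$related)
  }
})

test_that("modulation in a single direction suffices", {
  trials <- make_manual_trials(80)
  set.seed(55)
  cell <- flat_cell(trials)
  # add a strong transient only on direction-3 trials
  t3 <- trials$t_sacc[trials$direction == 3]
  extra <- unlist(lapply(t3, function(t0) runif(12, t0, t0 + 0.15)))
  cell$ss_times <- sort(c(cell$ss_times, extra))
  res <- classify_saccade_related(cell)
  expect_true(res$related)
  expect_lt(res$p[4], 0.05)
})

test_that("epoch classification recovers facilitation and suppression", {
  fac <- cell_config(baseline_rate_ss = 55,
                     instruction_profile = "facilitation",
                     instruction_gain = 20,
                     saccade_profile = "facilitation", saccade_gain = 30,
                     cs_baseline = 0)
  sup <- cell_config(baseline_rate_ss = 65,
                     instruction_profile = "suppression",
                     instruction_gain = 20,
                     saccade_profile = "suppression", saccade_gain = 25,
                     cs_baseline = 0)
  cell_f <- make_cell(fac, n_blocks = 8, seed = 2)  # 64 trials/condition
  cell_s <- make_cell(sup, n_blocks = 8, seed = 3)
  for (cond in c("pro", "anti")) {
    expect_equal(classify_epoch_response(cell_f, "instruction", cond),
                 "facilitation")
    expect_equal(classify_epoch_response(cell_f, "saccade", cond),
                 "facilitation")
    expect_equal(classify_epoch_response(cell_s, "instruction", cond),
                 "suppression")
    expect_equal(classify_epoch_response(cell_s, "saccade", cond),
                 "suppression")
  }
  # identical windows by construction -> none
  trials <- make_manual_trials(40)
  sym <- make_manual_cell(
    sort(unlist(lapply(trials$t_sacc, function(t0)
      c(t0 - 0.075, t0 + 0.075)))),  # one spike in each paired window
    numeric(0), trials)
  expect_equal(classify_epoch_response(sym, "saccade", "pro"), "none")
  # too few paired trials -> indeterminate
  few <- make_manual_cell(runif(20, 0, 10), numeric(0),
                          make_manual_trials(4))
  expect_true(is.na(classify_epoch_response(few, "saccade", "pro")))
})

test_that("ramping detection: exact line, null calibration, recovery", {
  # exactly linear binned rate -> R^2 = 1
  trials <- make_manual_trials(2)
  spikes <- unlist(lapply(seq_len(nrow(trials)), function(k) {
    e <- trials$t_target_on[k]
    unlist(lapply(1:10, function(j) {
      # j spikes in bin j (bins of 30 ms spanning [-0.3, 0))
      e - 0.3 + (j - 1) * 0.03 + (seq_len(j) - 0.5) * 0.03 / j
    }))
  }))
  lin <- make_manual_cell(sort(spikes), numeric(0), trials)
  res <- classify_ramping(lin, "pro")
  expect_true(res$ramping)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_gt(res$slope, 0)

  # constant rate + Poisson noise is almost never called ramping
  trials50 <- make_manual_trials(100)
  set.seed(71)
  fp <- vapply(seq_len(40), function(i) {
    classify_ramping(flat_cell(trials50), "pro")$ramping
  }, logical(1))
  expect_lte(mean(fp), 1 / 40)

  # a strong generator ramp is recovered with its slope
  cfg <- cell_config(baseline_rate_ss = 60, instruction_profile = "ramp",
                     ramp_slope = 150, cs_baseline = 0)
  hits <- 0; slopes <- numeric(0)
  for (seed in 1:6) {
    cell <- make_cell(cfg, n_blocks = 10, seed = seed)  # 80/condition
    r <- classify_ramping(cell, "pro")
    hits <- hits + r$ramping
    slopes <- c(slopes, r$slope)
  }
  expect_gte(hits, 5)
  expect_lt(abs(mean(slopes) - 150) / 150, 0.25)
})

test_that("condition-difference K-S: null behaviour and power", {
  trials <- make_manual_trials(80)
  cell <- flat_cell(trials, seed = 9)
  expect_gt(test_condition_difference(cell), 0.05)
  # duplicated data can never be significant
  trials_dup <- trials
  trials_dup$condition <- rep(c("pro", "anti"), each = 40)
  trials_dup$t_sacc <- rep(trials$t_sacc[1:40], 2)
  expect_equal(suppressWarnings(
    ks.test(1:10, 1:10)$p.value), 1)

  # a 1.5x pro/anti gain on ~60 trials per condition is detected
  cfg <- cell_config(baseline_rate_ss = 50, condition_gain = 1.5,
                     cs_baseline = 0)
  detected <- vapply(1:5, function(seed) {
    cell <- make_cell(cfg, n_blocks = 8, seed = seed)
    test_condition_difference(cell) < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.8)
})

test_that("classify_cell assembles a consistent per-condition table", {
  cfg <- cell_config(baseline_rate_ss = 60,
                     saccade_profile = "facilitation", saccade_gain = 30)
  cell <- make_cell(cfg, n_blocks = 8, seed = 17)
  df <- classify_cell(cell)
  expect_equal(nrow(df), 2L)
  expect_setequal(df$condition, c("pro", "anti"))
  expect_true(all(df$included))
  expect_true(all(df$baseline_rate > 40 & df$baseline_rate < 80))
  expect_true(all(df$condition_diff_p >= 0 & df$condition_diff_p <= 1))
})
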