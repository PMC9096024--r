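# Synthetic session generator: trial schedules, minimum-jerk eye traces, and
# inhomogeneous-Poisson Purkinje cell spike trains with ground-truth labels.

#' Generate a balanced pro-/anti-saccade trial schedule
#'
#' Each block contains all 16 combinations of 8 target directions (45 deg
#' steps, 0 = rightward) and 2 conditions (pro, anti) in random order.
#' Instruction durations are drawn uniformly on `[0.3, 0.5]` s; the go cue
#' follows target onset by exactly 100 ms; consecutive trials are separated
#' by the configured intertrial interval.
#'
#' @param n_blocks number of blocks (>= 1); the schedule has `16 * n_blocks`
#'   trials.
#' @param kin a [kinematics_config()].
#' @param seed integer seed for the schedule stream.
#' @return a data.frame of trial records with columns `trial_id`, `condition`,
#'   `direction`, `target_amplitude` (filled by [simulate_eye_trace()]),
#'   `t_fix_on`, `t_target_on`, `t_go`, `instruction_duration`, `t_trial_end`,
#'   `outcome` (initially `"pending"`), and ground-truth placeholders.
#' @export
generate_schedule <- function(n_blocks, kin = kinematics_config(), seed = 1) {
  if (length(n_blocks) != 1L || is.na(n_blocks) || n_blocks < 1) {
    stop_invalid("n_blocks must be a positive integer")
  }
  n_blocks <- as.integer(n_blocks)
  set.seed(split_seed(seed, 1L))
  base <- expand.grid(direction = 0:7, condition = c("pro", "anti"),
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    base[sample.int(nrow(base)), , drop = FALSE]
  }))
  n <- nrow(rows)
  instr <- runif(n, 0.3, 0.5)
  # Per-trial span: pre-fix margin + instruction + 100 ms fix hold + post-go
  # tail; trials are laid out back to back separated by the ITI.
  span <- instr + 0.1 + kin$post_go
  t_fix <- kin$pre_fix + cumsum(c(0, head(span + kin$iti, -1)))
  trials <- data.frame(
    trial_id = seq_len(n),
    condition = rows$condition,
    direction = rows$direction,
    target_amplitude = NA_real_,
    t_fix_on = t_fix,
    t_target_on = t_fix + instr,
    t_go = t_fix + instr + 0.1,
    instruction_duration = instr,
    t_trial_end = t_fix + span,
    outcome = "pending",
    t_sacc_true = NA_real_,
    rt_true = NA_real_,
    amplitude_true = NA_real_,
    duration_true = NA_real_,
    peak_velocity_true = NA_real_,
    wrong_direction = FALSE,
    stringsAsFactors = FALSE
  )
  trials
}

min_jerk_pos <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# Draw (amplitude, duration) from the condition's bivariate normal; values
# outside physical ranges are clipped (count recorded). Clipping, unlike
# rejection, barely moves the means.
draw_amp_dur <- function(n, kin, condition) {
  ma <- kin$amp_mean[[condition]]; sa <- kin$amp_sd[[condition]]
  md <- kin$dur_mean[[condition]]; sdd <- kin$dur_sd[[condition]]
  rho <- ad_rho(kin, condition)
  z1 <- rnorm(n); z2 <- rnorm(n)
  a <- ma + sa * z1
  d <- md + sdd * (rho * z1 + sqrt(1 - rho^2) * z2)
  clipped <- sum(a < 0.5 | d < 0.012 | d > 0.250)
  list(amplitude = pmax(a, 0.5),
       duration = pmin(pmax(d, 0.012), 0.250),
       clipped = clipped)
}

#' Simulate one trial's eye-position trace
#'
#' Gaze sits at the fixation point with Gaussian positional noise; at
#' `t_go + RT` a minimum-jerk saccade of drawn amplitude and duration is
#' launched toward the target (pro) or its mirror position (anti). Reaction
#' time is drawn from the condition's truncated normal (floor `rt_floor`);
#' amplitude and duration jointly from the condition's bivariate normal (see
#' [kinematics_config()]). With probability `p_wrong_direction` the saccade
#' goes the task-inappropriate way and the trial becomes an error when
#' scored. Ground-truth kinematics are written back onto the returned trial.
#'
#' @param trial a one-row trial record from [generate_schedule()].
#' @param kin a [kinematics_config()].
#' @param seed integer seed for this trial's stream.
#' @return a list with elements `trace` (an `eye_trace`) and `trial` (the
#'   record updated with ground truth).
#' @export
simulate_eye_trace <- function(trial, kin = kinematics_config(), seed = 1) {
  stopifnot(nrow(trial) == 1L)
  if (!(trial$t_fix_on < trial$t_target_on && trial$t_target_on < trial$t_go)) {
    stop_invalid("trial has invalid event times")
  }
  set.seed(seed)
  fs <- kin$sampling_rate
  t0 <- trial$t_fix_on - kin$pre_fix
  tt <- seq(t0, trial$t_trial_end, by = 1 / fs)
  cond <- trial$condition
  rt <- rtruncnorm_lower(1, kin$rt_mean[[cond]], kin$rt_sd[[cond]],
                         kin$rt_floor)
  ad <- draw_amp_dur(1, kin, cond)
  amp <- ad$amplitude; dur <- ad$duration
  wrong <- runif(1) < kin$p_wrong_direction
  theta <- trial$direction * 45 * pi / 180
  # Target sits along `theta`; a correct prosaccade goes toward it, a correct
  # antisaccade toward the mirror position. Wrong-direction trials flip sign.
  sgn <- if (cond == "pro") 1 else -1
  if (wrong) sgn <- -sgn
  onset <- trial$t_go + rt
  x <- numeric(length(tt)); y <- numeric(length(tt))
  executed <- onset + dur <= trial$t_trial_end
  if (executed) {
    prof <- min_jerk_pos((tt - onset) / dur)
    x <- sgn * amp * cos(theta) * prof
    y <- sgn * amp * sin(theta) * prof
  }
  if (kin$fixation_noise_sd > 0) {
    x <- x + rnorm(length(tt), 0, kin$fixation_noise_sd)
    y <- y + rnorm(length(tt), 0, kin$fixation_noise_sd)
  }
  trace <- structure(
    list(time = tt, x = x, y = y, sampling_rate = fs,
         speed = NULL, acceleration = NULL, preprocessed = FALSE,
         trial_id = trial$trial_id),
    class = "eye_trace"
  )
  trial$target_amplitude <- amp
  if (executed) {
    trial$t_sacc_true <- onset
    trial$rt_true <- rt
    trial$amplitude_true <- amp
    trial$duration_true <- dur
    trial$peak_velocity_true <- 1.875 * amp / dur
  }
  trial$wrong_direction <- wrong
  list(trace = trace, trial = trial)
}

# Piecewise SS/CS rate for one cell over the session, on a 1 ms grid.
cell_rate_vectors <- function(trials, cfg, dt = 0.001) {
  t_end <- max(trials$t_trial_end) + 0.5
  n <- ceiling(t_end / dt)
  tg <- (seq_len(n) - 0.5) * dt
  ss <- rep(cfg$baseline_rate_ss, n)
  cs <- rep(cfg$cs_baseline, n)
  idx <- function(a, b) {
    i0 <- max(1L, floor(a / dt) + 1L); i1 <- min(n, ceiling(b / dt))
    if (i1 < i0) integer(0) else i0:i1
  }
  for (k in seq_len(nrow(trials))) {
    tr <- trials[k, ]
    t_sacc <- tr$t_sacc_true
    if (cfg$instruction_profile == "facilitation") {
      i <- idx(tr$t_fix_on, tr$t_target_on)
      ss[i] <- ss[i] + cfg$instruction_gain
    } else if (cfg$instruction_profile == "suppression") {
      i <- idx(tr$t_fix_on, tr$t_target_on)
      ss[i] <- ss[i] - cfg$instruction_gain
    } else if (cfg$instruction_profile == "ramp") {
      ramp_end <- if (is.na(t_sacc)) tr$t_go + 0.3 else t_sacc
      i <- idx(tr$t_fix_on, ramp_end)
      ss[i] <- ss[i] + cfg$ramp_slope * (tg[i] - tr$t_fix_on)
    }
    if (cfg$saccade_profile != "none" && !is.na(t_sacc)) {
      g <- cfg$saccade_gain *
        (if (cfg$saccade_profile == "suppression") -1 else 1)
      if (cfg$tuning_gain > 0) {
        th <- tr$direction * 45 - cfg$tuning_pref
        g <- g * (1 + cfg$tuning_gain * cos(th * pi / 180))
      }
      ctr <- t_sacc + cfg$saccade_latency
      i <- idx(ctr - 4 * cfg$saccade_width, ctr + 4 * cfg$saccade_width)
      ss[i] <- ss[i] + g * exp(-0.5 * ((tg[i] - ctr) / cfg$saccade_width)^2)
    }
    if (cfg$condition_gain != 1 && tr$condition == "pro") {
      i <- idx(tr$t_fix_on, tr$t_trial_end)
      ss[i] <- ss[i] * cfg$condition_gain
    }
    if (cfg$cs_gain_instruction != 0) {
      i <- idx(tr$t_fix_on + 0.05, tr$t_fix_on + 0.35)
      cs[i] <- cs[i] + cfg$cs_gain_instruction
    }
    if (cfg$cs_gain_saccade != 0 && !is.na(t_sacc)) {
      i <- idx(t_sacc - 0.15, t_sacc + 0.15)
      cs[i] <- cs[i] + cfg$cs_gain_saccade
    }
  }
  list(t = tg, ss = pmax(ss, 0), cs = pmax(cs, 0), dt = dt, t_end = t_end)
}

sample_poisson_train <- function(tg, rate, dt) {
  counts <- rpois(length(rate), rate * dt)
  i <- which(counts > 0L)
  if (length(i) == 0L) return(numeric(0))
  i <- rep(i, counts[i])
  sort((i - 1) * dt + runif(length(i)) * dt)
}

#' Simulate one Purkinje cell's spike trains
#'
#' Simple- and complex-spike times are drawn from inhomogeneous Poisson
#' processes whose rates are the cell's baseline plus epoch-locked profiles
#' aligned to each trial's events and ground-truth saccade onset (see
#' [cell_config()]). Every CS silences SS firing for `cs_pause` seconds,
#' emulating the climbing-fibre pause.
#'
#' @param trials trial data.frame carrying ground-truth saccade onsets
#'   (`t_sacc_true`), e.g. from [generate_population()].
#' @param cfg a [cell_config()].
#' @param seed integer seed.
#' @param cell_id identifier stored on the recording.
#' @return an object of class `cell_recording`: list with `cell_id`,
#'   `region`, `ss_times`, `cs_times`, `trials`, `duration`, `ground_truth`.
#' @export
simulate_pc <- function(trials, cfg = cell_config(), seed = 1,
                        cell_id = "cell_1") {
  if (nrow(trials) == 0L) stop_invalid("trials must be non-empty")
  set.seed(seed)
  rv <- cell_rate_vectors(trials, cfg)
  ss <- sample_poisson_train(rv$t, rv$ss, rv$dt)
  cs <- sample_poisson_train(rv$t, rv$cs, rv$dt)
  if (cfg$cs_pause > 0 && length(cs) > 0L && length(ss) > 0L) {
    # remove SS in (cs, cs + pause]: compare each SS to the preceding CS
    prev <- findInterval(ss, cs)
    has_prev <- prev > 0L
    gap <- ss - cs[pmax(prev, 1L)]
    drop <- has_prev & gap > 0 & gap <= cfg$cs_pause
    ss <- ss[!drop]
  }
  structure(
    list(cell_id = cell_id, region = cfg$region,
         ss_times = ss, cs_times = cs, trials = trials,
         duration = rv$t_end, ground_truth = cfg),
    class = "cell_recording"
  )
}

#' Generate a full synthetic recording session
#'
#' One shared trial schedule and eye-trace set drive independent simulations
#' of all requested cells, so every cell sees the same behaviour. All
#' randomness derives from `seed` through [split_seed()] (stream 1 =
#' schedule, streams `100 + trial_id` = eye traces, streams `10000 + i` =
#' cells), so the same seed reproduces the session exactly.
#'
#' @param pop_spec named list mapping region (`"medial"`, `"lateral"`) to a
#'   list of [cell_config()] objects.
#' @param kin a [kinematics_config()].
#' @param n_blocks number of 16-trial blocks.
#' @param seed integer session seed.
#' @return an object of class `pc_session`: list with `trials`, `eye`
#'   (list of `eye_trace` indexed by trial), `cells` (list of
#'   `cell_recording`), `kin`, and `seed`.
#' @export
generate_population <- function(pop_spec, kin = kinematics_config(),
                                n_blocks = 10, seed = 1) {
  if (length(pop_spec) == 0L || sum(lengths(pop_spec)) == 0L) {
    stop_invalid("pop_spec must request at least one cell")
  }
  trials <- generate_schedule(n_blocks, kin, seed)
  eye <- vector("list", nrow(trials))
  for (k in seq_len(nrow(trials))) {
    sim <- simulate_eye_trace(trials[k, ], kin,
                              seed = split_seed(seed, 100L + k))
    eye[[k]] <- sim$trace
    trials[k, ] <- sim$trial
  }
  cells <- list()
  i <- 0L
  for (region in names(pop_spec)) {
    for (cfg in pop_spec[[region]]) {
      i <- i + 1L
      cfg$region <- region
      cells[[i]] <- simulate_pc(trials, cfg,
                                seed = split_seed(seed, 10000L + i),
                                cell_id = sprintf("%s_%02d", region, i))
    }
  }
  structure(list(trials = trials, eye = eye, cells = cells,
                 kin = kin, seed = seed),
            class = "pc_session")
}

#' Score trials from simulator ground truth
#'
#' Bypasses eye-trace detection: sets each trial's saccade onset and outcome
#' directly from the generator's ground truth (reaction-time floor and
#' wrong-direction flag applied). Useful for spike-train analyses that should
#' not depend on the detection chain.
#'
#' @param session a `pc_session`.
#' @param rt_floor anticipatory exclusion threshold in seconds.
#' @return the session with `trials$outcome` in
#'   `{"correct", "error", "excluded"}` and `t_sacc` set, propagated to all
#'   cell recordings.
#' @export
attach_ground_truth <- function(session, rt_floor = 0.100) {
  tr <- session$trials
  tr$t_sacc <- tr$t_sacc_true
  tr$rt <- tr$rt_true
  tr$amplitude <- tr$amplitude_true
  tr$peak_velocity <- tr$peak_velocity_true
  tr$duration <- tr$duration_true
  tr$outcome <- ifelse(is.na(tr$t_sacc_true), "error",
                ifelse(tr$rt_true < rt_floor, "excluded",
                ifelse(tr$wrong_direction, "error", "correct")))
  session$trials <- tr
  session$cells <- lapply(session$cells, function(cell) {
    cell$trials <- tr
    cell
  })
  session
}
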