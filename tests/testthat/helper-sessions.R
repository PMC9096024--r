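# Shared fixtures: small synthetic sessions built in code.

# A noiseless eye trace holding one minimum-jerk saccade; returns the trace
# plus its ground truth.
make_minjerk_trace <- function(amplitude, duration, onset = 0.4,
                               total = 1.0, fs = 350, theta_deg = 0,
                               noise_sd = 0) {
  tt <- seq(0, total, by = 1 / fs)
  tau <- pmin(pmax((tt - onset) / duration, 0), 1)
  prof <- amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  th <- theta_deg * pi / 180
  x <- prof * cos(th)
  y <- prof * sin(th)
  if (noise_sd > 0) {
    x <- x + rnorm(length(tt), 0, noise_sd)
    y <- y + rnorm(length(tt), 0, noise_sd)
  }
  structure(list(time = tt, x = x, y = y, sampling_rate = fs,
                 speed = NULL, acceleration = NULL, preprocessed = FALSE,
                 trial_id = 1L),
            class = "eye_trace")
}

# A quiet session (no fixation noise removal needed) for spike-only tests:
# ground-truth scoring, no detection chain.
make_spike_session <- function(cfgs, n_blocks = 4, seed = 1,
                               kin = kinematics_config()) {
  pop <- list(medial = cfgs)
  s <- generate_population(pop, kin, n_blocks = n_blocks, seed = seed)
  attach_ground_truth(s)
}

# One simulated cell over a fresh schedule, ground-truth scored.
make_cell <- function(cfg, n_blocks = 4, seed = 1,
                      kin = kinematics_config()) {
  s <- make_spike_session(list(cfg), n_blocks = n_blocks, seed = seed,
                          kin = kin)
  s$cells[[1]]
}

# Minimal hand-built cell: spikes + a scored trial table, bypassing the
# generator entirely.
make_manual_cell <- function(ss_times, cs_times, trials,
                             region = "medial", duration = NULL) {
  if (is.null(duration)) duration <- max(trials$t_trial_end)
  structure(list(cell_id = "manual", region = region,
                 ss_times = sort(ss_times), cs_times = sort(cs_times),
                 trials = trials, duration = duration,
                 ground_truth = NULL),
            class = "cell_recording")
}

# A scored trial table with regular timing, no generator involved.
make_manual_trials <- function(n, iti = 2, instr = 0.4, rt = 0.2) {
  t_fix <- iti * seq_len(n)
  data.frame(
    trial_id = seq_len(n),
    condition = rep(c("pro", "anti"), length.out = n),
    direction = ((seq_len(n) - 1) %/% 2) %% 8,
    target_amplitude = 8,
    t_fix_on = t_fix,
    t_target_on = t_fix + instr,
    t_go = t_fix + instr + 0.1,
    instruction_duration = instr,
    t_trial_end = t_fix + instr + 0.1 + 1.0,
    outcome = "correct",
    t_sacc = t_fix + instr + 0.1 + rt,
    rt = rt,
    stringsAsFactors = FALSE
  )
}
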