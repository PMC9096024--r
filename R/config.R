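#' Saccade kinematics configuration
#'
#' Per-condition distributions for reaction time, amplitude, and duration of
#' pro- and anti-saccades, plus session-level acquisition parameters. The
#' defaults are the summary moments of a pro-/anti-saccade data set recorded
#' from head-fixed macaques: reaction time 178.4 +/- 70.6 ms (pro) and
#' 236.6 +/- 72.7 ms (anti); amplitude 5.8 +/- 2.3 deg (pro) and
#' 9.5 +/- 4.1 deg (anti); duration 34.7 +/- 7.9 ms (pro) and
#' 69.8 +/- 24 ms (anti). Peak velocity is never a parameter: it emerges from
#' the minimum-jerk velocity profile as `1.875 * amplitude / duration`.
#'
#' Amplitude and duration are drawn jointly from a bivariate normal with the
#' configured marginal moments and correlation `ad_correlation`. The default
#' `"auto"` sets the correlation to `CV_D / CV_A` (coefficient of variation of
#' duration over that of amplitude, capped at 0.95), the value at which the
#' second-order bias of `E[A/D]` relative to `mean(A)/mean(D)` cancels, so the
#' population mean peak velocity matches `1.875 * mean(A) / mean(D)`. This
#' mirrors the empirical main sequence, in which larger saccades last longer.
#'
#' @param rt_mean,rt_sd named numeric `c(pro=, anti=)`, reaction time moments
#'   in seconds. Draws are truncated below at `rt_floor`.
#' @param amp_mean,amp_sd amplitude moments in degrees.
#' @param dur_mean,dur_sd duration moments in seconds.
#' @param ad_correlation `"auto"` or a number in `[0, 0.95]`; amplitude-
#'   duration correlation per condition.
#' @param fixation_noise_sd positional noise SD in degrees added to every
#'   sample (video eye trackers typically show 0.03-0.1 deg RMS).
#' @param sampling_rate eye sampling rate in Hz.
#' @param rt_floor lower truncation of reaction-time draws, seconds.
#' @param p_wrong_direction probability that a trial's saccade is launched in
#'   the task-inappropriate direction (e.g. a reflexive prosaccade on an
#'   antisaccade trial); such trials score as errors. Default 0.06 emulates
#'   ~94% correct expert performance.
#' @param iti intertrial interval in seconds preceding each fixation onset;
#'   long enough that the baseline window 400-50 ms before trial onset always
#'   lies in the intertrial interval.
#' @param post_go trial time retained after the go cue, seconds.
#' @param pre_fix eye-trace time retained before fixation onset, seconds.
#' @param velocity_profile only `"min_jerk"` is implemented.
#' @return an object of class `kinematics_config`.
#' @export
kinematics_config <- function(rt_mean = c(pro = 0.1784, anti = 0.2366),
                              rt_sd = c(pro = 0.0706, anti = 0.0727),
                              amp_mean = c(pro = 5.8, anti = 9.5),
                              amp_sd = c(pro = 2.3, anti = 4.1),
                              dur_mean = c(pro = 0.0347, anti = 0.0698),
                              dur_sd = c(pro = 0.0079, anti = 0.0240),
                              ad_correlation = "auto",
                              fixation_noise_sd = 0.05,
                              sampling_rate = 350,
                              rt_floor = 0.100,
                              p_wrong_direction = 0.06,
                              iti = 1.5,
                              post_go = 1.0,
                              pre_fix = 0.6,
                              velocity_profile = "min_jerk") {
  velocity_profile <- match.arg(velocity_profile, "min_jerk")
  for (v in list(rt_sd, amp_sd, dur_sd)) {
    if (any(v <= 0)) stop_invalid("all kinematic SDs must be > 0")
  }
  if (sampling_rate <= 0) stop_invalid("sampling_rate must be > 0")
  cfg <- list(
    rt_mean = rt_mean, rt_sd = rt_sd,
    amp_mean = amp_mean, amp_sd = amp_sd,
    dur_mean = dur_mean, dur_sd = dur_sd,
    ad_correlation = ad_correlation,
    fixation_noise_sd = fixation_noise_sd,
    sampling_rate = sampling_rate,
    rt_floor = rt_floor,
    p_wrong_direction = p_wrong_direction,
    iti = iti, post_go = post_go, pre_fix = pre_fix,
    velocity_profile = velocity_profile
  )
  class(cfg) <- "kinematics_config"
  cfg
}

ad_rho <- function(kin, condition) {
  if (identical(kin$ad_correlation, "auto")) {
    cv_a <- kin$amp_sd[[condition]] / kin$amp_mean[[condition]]
    cv_d <- kin$dur_sd[[condition]] / kin$dur_mean[[condition]]
    min(cv_d / cv_a, 0.95)
  } else {
    min(max(as.numeric(kin$ad_correlation), 0), 0.95)
  }
}

#' Purkinje cell simulation configuration
#'
#' Describes one simulated Purkinje cell: baseline simple-spike (SS) rate,
#' epoch-locked modulation profiles, complex-spike (CS) behaviour, and the
#' post-CS pause in SS firing. Rates are clipped at zero after all
#' modulations.
#'
#' @param region `"medial"` (oculomotor vermis) or `"lateral"` (crus I/II).
#' @param baseline_rate_ss SS baseline in spikes/s (recorded cells sit around
#'   55-70 spks/s).
#' @param instruction_profile `"none"`, `"facilitation"`, `"suppression"`, or
#'   `"ramp"`; applied during the instruction period (fixation onset to
#'   target onset).
#' @param instruction_gain gain in spikes/s for facilitation/suppression.
#' @param ramp_slope slope in spikes/s per second for the `"ramp"` profile;
#'   the ramp grows from instruction onset and ends at the saccade.
#' @param saccade_profile `"none"`, `"facilitation"`, or `"suppression"`;
#'   a Gaussian rate transient of SD `saccade_width` centred
#'   `saccade_latency` after saccade onset.
#' @param saccade_gain transient amplitude in spikes/s (positive number; the
#'   sign is set by the profile).
#' @param saccade_latency seconds from saccade onset to the transient centre.
#' @param saccade_width SD of the rate transient in seconds.
#' @param condition_gain multiplicative factor applied to the whole SS rate
#'   during prosaccade trials (1 = no pro/anti difference).
#' @param cs_baseline CS baseline rate in Hz (~1 Hz for climbing-fibre input).
#' @param cs_gain_instruction,cs_gain_saccade additive CS rate change in Hz
#'   during the instruction window (50-350 ms after instruction onset) and
#'   the perisaccadic window (+/-150 ms around saccade onset).
#' @param cs_pause seconds of SS silencing after each CS (climbing-fibre
#'   pause).
#' @param tuning_gain optional cosine directional tuning depth in `[0, 1]`
#'   applied to the saccade transient; 0 disables tuning.
#' @param tuning_pref preferred direction in degrees.
#' @return an object of class `cell_config`.
#' @export
cell_config <- function(region = c("medial", "lateral"),
                        baseline_rate_ss = 60,
                        instruction_profile = c("none", "facilitation",
                                                "suppression", "ramp"),
                        instruction_gain = 0,
                        ramp_slope = 0,
                        saccade_profile = c("none", "facilitation",
                                            "suppression"),
                        saccade_gain = 0,
                        saccade_latency = 0.10,
                        saccade_width = 0.040,
                        condition_gain = 1,
                        cs_baseline = 1,
                        cs_gain_instruction = 0,
                        cs_gain_saccade = 0,
                        cs_pause = 0.015,
                        tuning_gain = 0,
                        tuning_pref = 0) {
  region <- match.arg(region)
  instruction_profile <- match.arg(instruction_profile)
  saccade_profile <- match.arg(saccade_profile)
  if (cs_pause < 0) stop_invalid("cs_pause must be >= 0")
  if (baseline_rate_ss < 0 || cs_baseline < 0) {
    stop_invalid("baseline rates must be >= 0")
  }
  cfg <- list(
    region = region,
    baseline_rate_ss = baseline_rate_ss,
    instruction_profile = instruction_profile,
    instruction_gain = instruction_gain,
    ramp_slope = ramp_slope,
    saccade_profile = saccade_profile,
    saccade_gain = saccade_gain,
    saccade_latency = saccade_latency,
    saccade_width = saccade_width,
    condition_gain = condition_gain,
    cs_baseline = cs_baseline,
    cs_gain_instruction = cs_gain_instruction,
    cs_gain_saccade = cs_gain_saccade,
    cs_pause = cs_pause,
    tuning_gain = tuning_gain,
    tuning_pref = tuning_pref
  )
  class(cfg) <- "cell_config"
  cfg
}
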