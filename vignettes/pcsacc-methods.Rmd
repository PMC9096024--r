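---
title: "Methods: simulating and analysing Purkinje cell activity in pro/anti-saccade tasks"
author: "pcsacc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing Purkinje cell activity in pro/anti-saccade tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcsacc)
```

# Overview

`pcsacc` analyses cerebellar Purkinje cell (PC) recordings made while a
subject performs randomly interleaved pro- and anti-saccades to eight
target directions. Because such recordings are scarce, the package pairs
every analysis stage with a synthetic-session generator that produces eye
traces and spike trains with known ground truth, so each stage can be
validated by recovery experiments rather than by eyeball. This vignette
documents the generative model, the analysis conventions, the numerical
choices, and what the validation does and does not establish.

# The task and the trial clock

A trial begins with a coloured fixation point whose colour instructs the
condition. After a uniformly distributed instruction period of 300–500 ms
the target appears in one of eight directions (45° apart); 100 ms later the
fixation point turns grey (the go cue) and the subject has 500 ms to
saccade to the target (pro) or its mirror position (anti), then hold within
6° for 100 ms. Reaction times under 100 ms are excluded as anticipatory
rather than counted as errors. Consecutive trials are separated by an
intertrial interval of 1.5 s (a configuration choice; the baseline window
400–50 ms before fixation onset must lie inside it).

# The synthetic-session generator

## Eye movements

Saccades follow a minimum-jerk position profile
$x(\tau) = A\,(10\tau^3 - 15\tau^4 + 6\tau^5)$, whose peak speed is
$V_p = \tfrac{15}{8} A / D$ for amplitude $A$ and duration $D$. Peak
velocity is therefore *emergent*: the generator never draws it.

Per condition, the defaults are the summary moments of macaque
pro-/anti-saccade behaviour in this task: reaction time
178.4 ± 70.6 ms (pro) and 236.6 ± 72.7 ms (anti); amplitude 5.8 ± 2.3°
(pro) and 9.5 ± 4.1° (anti); duration 34.7 ± 7.9 ms (pro) and
69.8 ± 24 ms (anti).

$A$ and $D$ are drawn *jointly* from a bivariate normal with those
marginals and correlation $\rho = \mathrm{CV}_D / \mathrm{CV}_A$ (pro
0.574, anti 0.797). The correlation matters: for independent draws the
delta method gives
$E[A/D] \approx \tfrac{\bar A}{\bar D}(1 + \mathrm{CV}_D^2 - \rho\,
\mathrm{CV}_A \mathrm{CV}_D)$, so independence would inflate the mean
emergent peak velocity by $\mathrm{CV}_D^2$ — about 5% (pro) and 12%
(anti) — whereas $\rho = \mathrm{CV}_D/\mathrm{CV}_A$ cancels the bias
exactly when $E[A\,|\,D]$ is linear in $D$ (which it is under the bivariate
normal, to all orders). This coupling also mirrors the empirical main
sequence, in which larger saccades last longer. Draws are clipped to
physical ranges ($A \ge 0.5°$, $12\,\mathrm{ms} \le D \le 250$ ms);
clipping, unlike rejection-resampling, leaves the means essentially
untouched.

Reaction times are normals truncated below at the 100 ms floor via
inverse-CDF sampling. The truncation shifts the mean upward by
$\sigma\,\phi(a)/(1-\Phi(a))$ with $a = (0.1-\mu)/\sigma$: +17.5 ms for
prosaccades and +5.1 ms for antisaccades at the defaults. Any comparison of
simulated mean reaction times against the configured means must add this
analytic bias; `scripts/acceptance.R` documents it in place.

Positional noise is white Gaussian with SD 0.05° per sample at 350 Hz, a
typical RMS figure for video-based infrared eye trackers. With probability
0.06 a trial's saccade is launched in the task-inappropriate direction
(emulating ~94% correct expert performance); such trials score as errors
unless the amplitude is so small (< 3°) that the wrong endpoint still falls
inside the 6° window — a property of the task's spatial rule, not of the
simulator.

## Spike trains

SS and CS trains are inhomogeneous Poisson processes sampled on a 1 ms
grid. The SS rate is a baseline (~55–70 spks/s) plus per-trial profiles:

- *instruction facilitation/suppression*: ±gain during the instruction
  period;
- *ramp*: rate increasing linearly from instruction onset (spks/s per s)
  until the saccade;
- *saccade facilitation/suppression*: a Gaussian transient (SD 40 ms)
  of ±gain centred `latency` after saccade onset;
- *condition gain*: a multiplicative pro-trial factor over the whole trial
  (the substrate for pro/anti decoding and the modulation ratio);
- optional cosine directional tuning of the saccade transient.

Rates are clipped at zero. The CS rate is a ~1 Hz baseline plus additive
gains in the instruction window (50–350 ms after instruction onset) and the
perisaccadic window (±150 ms). Every CS deletes SS spikes in the following
`cs_pause` seconds (default 15 ms), emulating the climbing-fibre pause that
identifies a PC.

All randomness flows from one session seed through a documented splitting
rule (`split_seed`): stream 1 is the schedule, streams 100 + *k* the eye
traces, streams 10000 + *i* the cells. The same seed reproduces a session
exactly, including its serialized form.

## What the generator does not emulate

No biophysics (no bistability, no spikelets), no eyelid artefacts, no
drift or blinks in the eye signal, no reward- or error-related CS
signalling, no session-scale nonstationarity, and error trials differ from
correct ones only in saccade direction. Recovery results therefore validate
the *estimators* under the stated statistical structure; they do not show
that real recordings satisfy that structure.

# Analysis conventions

## Eye kinematics

Position is low-pass filtered with a zero-phase 30-tap FIR and then
Savitzky–Golay smoothed (order 2, 20 ms window = 7 samples at 350 Hz);
speed is the Euclidean norm of the first-difference velocity; acceleration
is median-filtered over 3 samples. The FIR cutoff is 60 Hz: the design
requirement is that the peak speed of a minimum-jerk saccade of typical
duration survive the chain within 1% of the analytic $1.875\,A/D$, and a
50 Hz cutoff measurably clips the shortest (~35 ms) prosaccades, while
60 Hz preserves them (the filter chain is validated against the analytic
oracle in the test suite). The filter is normalised to exact unit DC gain
so constants and linear ramps pass through unchanged. Peak velocity is
refined by parabolic interpolation around the sample maximum, which removes
the half-sample discretisation loss.

Detection thresholds are adaptive: the high threshold is 6 SD of the
session's fixation-speed noise, pooled over the instruction-period windows.
Because speed is a non-negative norm, its fixation-noise floor has a
positive mean (Rayleigh-like), so both thresholds are offset by that mean
(`mean + k·SD`); without the offset, onset refinement walks backward
through the noise floor indefinitely. Supra-threshold epochs closer than
10 ms are merged, epochs shorter than 10 ms discarded, and onsets/offsets
refined outward to the 1 SD crossing. These refinement constants are
conventions, not inferences; they are exposed as arguments.

## Spike density functions and windows

SDFs are sums of unit-mass Gaussians (σ = 50 ms for SS; 25 ms for the much
sparser CS) evaluated on a 1 ms grid, with no edge renormalisation: the
integral equals the spike count only when the window extends well past the
spikes. Note that a window extending 4σ past the spikes conserves mass only
to ~6×10⁻⁵ (the Gaussian tail); 5σ or more is needed for 10⁻⁶-level
conservation, and the tests use that. All analysis windows are half-open
[a, b); trial-averaged SDFs collect spikes from a 4σ-padded window so the
estimate inside the window carries no edge bias.

## Classification rules

- *Inclusion*: ≥ 5 correct trials in every direction × condition cell.
- *Saccade-related*: per direction, unpaired rank-sum of per-trial rates,
  baseline [−400, −50) ms before fixation onset vs [0, 150) ms after
  saccade onset (rates, not counts, because the windows differ in length);
  related iff any of the eight uncorrected p-values < 0.05. For a flat cell
  this fires at the family-wise rate 1 − 0.95⁸ ≈ 0.34 — a property of the
  uncorrected rule itself, reproduced (not fixed) here; a
  Benjamini–Hochberg switch is available for users.
- *Epoch class*: paired signed-rank between [−400, 0) ms before instruction
  onset and the last 300 ms of the instruction (instruction epoch), or
  between [−150, 0) and [0, 150) ms around saccade onset (saccade epoch);
  facilitation/suppression by the sign of a significant difference. The
  instruction-epoch reading (pre-onset baseline vs late instruction, as
  paired per-trial means) is an interpretive choice.
- *Ramping*: OLS on the trial-averaged rate over the last 300 ms of
  instruction, ramping iff R² > 0.75. The rate is averaged in 30 ms bins
  (10 points) rather than read off the σ = 50 ms SDF: smoothed noise is
  correlated over most of a 300 ms window and routinely masquerades as a
  line, which would make the null false-positive rate of the R² rule about
  30%; with independent bin noise the null R² follows its textbook Beta
  distribution and flat cells essentially never pass. The flip side is a
  sharp power threshold: with 60–80 trials per condition the rule reliably
  detects ramps whose rise over the window is comparable to the epoch
  gains (tens of spks/s), while shallow ramps (e.g. 12 spks/s rise) sit
  below the R² = 0.75 boundary at these trial counts and are detected only
  sporadically, whatever the estimator.
- *Condition difference*: two-sample Kolmogorov–Smirnov on per-trial
  saccade-window spike counts, pro vs anti. Spike counts are discrete, so
  the asymptotic K-S is conservative; at ~60 trials per condition its
  empirical type-I rate is close to nominal (the calibration the test
  suite checks), and it becomes markedly conservative at several hundred
  trials.

## Population metrics

Modulation ratio = mean saccade-window SS rate (pro) / (anti); latencies
are the argmax/argmin of the saccade-aligned trial-average SDF within
(0, 300] ms (the 300 ms cap is a convention); population traces are
z-scored against each cell's own intertrial baseline mean/SD before
averaging; Cohen's d uses the pooled SD. Kinematic regressions correct
firing as `rate / β` and are undefined when β is indistinguishable from
zero.

## CS analyses

CS inclusion needs a session-wide CS rate ≥ 0.5 Hz (boundary inclusive)
and the 5-trial rule. Epoch modulation compares the trial-averaged CS SDF
in the epoch window against mean ± 3 SD of the intertrial baseline. The
baseline *mean* uses the 500 ms before fixation onset; the baseline *SD* is
estimated over the full 1.45 s intertrial stretch, because 500 ms of a
~1 Hz density smoothed at σ = 25 ms holds only ~10 independent kernel
widths and the resulting SD noise would more than double the false-positive
rate of the ±3 SD rule. Reciprocity takes the extremal (sign-retaining)
CS-SDF deviation in the epoch window, the extremal SS-SDF deviation within
±150 ms of the CS peak, and their product; negative products mark
reciprocal modulation. The saccade-on-instruction regression applies
exactly one Cook's-distance (> 3× mean) exclusion pass — iterating the
exclusion changes results and is deliberately not done.

A caveat worth knowing when reading reciprocity R² values at realistic cell
counts: under independence the OLS R² at n = 16 follows Beta(1/2, 7), which
exceeds 0.15 with probability 0.138, and the outlier pass (which
preferentially removes the points keeping R² low) raises that further. A
single modest R² at n = 16 is therefore weak evidence of coupling on its
own; the regression's value lies in comparing regions/conditions.

## Demixed PCA

The population PSTH tensor holds trial-averaged rates in 100 ms bins
aligned to instruction offset (default window [−0.6, 0.8) s), directions
pooled, for neurons with ≥ 5 correct trials in both conditions. After
neuron-wise mean-centring, the matrix splits into exactly two
marginalizations — condition-independent (the per-time mean over the two
conditions, replicated) and stimulus (the residual) — matching the
two-condition design; with correct-only trials there is no
decision/interaction marginalization. Per marginalization the
ridge-regularised reduced-rank problem
$\min \lVert X_\phi - F D X \rVert^2 + \lambda \lVert D \rVert^2$ is
solved in closed form: $C = X_\phi X^\top (X X^\top + \lambda I)^{+}$, then
the rank-q truncation via the SVD of $CX$, giving encoder columns $F$ and
decoder rows $D$. With a single marginalization and λ = 0 this reduces
exactly to PCA (a tested identity). λ is selected on a log grid by
held-out-trial reconstruction cross-validation, with a fixed override for
deterministic tests; for *decoding*, heavier shrinkage than the
reconstruction optimum often helps, because classification margins benefit
from pulling the decoder toward the population-uniform axis, and the tests
pin λ where they need determinism.

Decoding is leave-group-out: per iteration one random trial per neuron and
condition forms the test pseudo-trial, the stimulus decoder axes are refit
on the training-trial averages — held-out trials never influence the axis;
skipping this refit leaks the test trials into the axis and biases
accuracy — and test projections are classified to the nearer class mean,
bin by bin. Significance uses 100 within-neuron label shuffles with a
max-over-time statistic (accuracy must exceed the 95th percentile of the
shuffles' time-course maxima), which controls the family-wise error across
bins. Per-bin accuracies on null data wobble around 0.5 more than the
binomial SE suggests, because CV iterations reuse the same trials; the mean
across bins concentrates at chance.

# Degenerate inputs and error behaviour

Traces shorter than a filter window, empty SDF windows, unknown alignment
events, insufficient fixation data, non-positive noise SDs, and too few
cells for a regression raise errors with explicit messages. Too few CS for
the pause check returns indeterminate (`NA`), which is distinct from
`FALSE`. Cells failing the pause check are flagged but retained for SS
analyses. A session whose reaction-time floor excludes every trial yields
a report with an explicit empty-input status rather than a crash.

# Validation scale

The test suite validates at sizes chosen to make recovery statistics
stable while keeping the suite fast: detection fidelity on ~120 noiseless
saccades plus 128-trial noisy sessions; classification recovery on a
200-cell population at 64 trials per condition with gains ≥ 25 spks/s;
K-S calibration on 1000 null cells at 60 trials per condition; reciprocity
null behaviour on 200 regressions of 16 cells; dPCA decoding on 40-neuron
populations. The acceptance script simulates 260 blocks (4160 trials,
≥ 2000 per condition) through the full detection chain.

# Known limitations

- The generator's trial-to-trial independence understates the slow rate
  drifts of real recordings; baseline-window statistics are accordingly
  optimistic.
- The ±3 SD CS modulation rule and the R² > 0.75 ramping rule are sharp
  thresholds; cells near the boundary flip classification under
  resampling. Effect sizes (products, slopes, ratios) are the stable
  quantities.
- The 6° correctness window cannot distinguish a correct small saccade
  from a wrong-direction saccade of amplitude < 3°.
- dPCA variance percentages depend on the window and bin width; comparing
  them across data sets requires identical settings.
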