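---
title: "Methods: brain-body dynamics around self-caught mind-wandering reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-body dynamics around self-caught mind-wandering reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(selfcaught)
```

This vignette explains the models and procedures implemented in
`selfcaught`, the assumptions behind them, the parameters that matter,
and the design decisions taken where the design was genuinely open.  It
states no empirical result that the package's tests and acceptance
script do not themselves compute.

## The paradigm and the state windows

Participants perform a monotonous task (respond to tones, or to each
end of exhalation) and press a report key whenever they become aware
that their mind has wandered.  Analysis windows are anchored to those
reports: mind wandering (MW) is taken as the period 5-9 s before the
report, the transition to awareness ("aware") as 1-5 s before it, and
focused task performance ("focus") as the 4 s from the first tone after
the task resumes.  The second immediately before the report is never
analyzed, because the motor preparation of the report contaminates it.
Reports arriving within 10 s of the previous report are excluded from
signal epoching (the windows would overlap the previous episode); they
still count behaviorally.  Windows are half-open `[start, end)` on the
sample grid - the boundaries given above are whole seconds, and a
half-open convention makes the MW and aware windows partition their 8 s
exactly.

## Behavioral metrics

Reaction-time variability is the coefficient of variation
`sd(RT)/mean(RT)` within each state, with the sample (n-1) standard
deviation; a state with fewer than two matched reaction times yields
`NA` rather than a fabricated zero.  Presses are matched to the most
recent unmatched tone within a latency cap (default 1.2 s, the minimum
inter-stimulus interval).  Heartbeat-counting accuracy is
`1 - |actual - reported| / actual` per trial, averaged over trials; it
is 1 for perfect counting, symmetric in the sign of the error, and
unbounded below.  The a priori power analysis utility
(`required_sample_size()`) inverts the noncentral-t power function of a
one-sample/paired two-tailed test; at a medium effect (d = 0.5),
alpha = .05 and power .80 it returns n = 34.

## Respiration

The belt signal is preprocessed in three steps, in order: a 25-ms
moving-average smooth, a global linear detrend (the fitted regression
line is subtracted), and a local drift correction subtracting a 60-s
sliding mean.  All windows use only samples that exist, so edges are
corrected by the valid-window mean rather than padded values.

Phase detection is extrema-based: inhalation runs from each trough to
the next peak, exhalation from peak to trough.  Noise extrema are
rejected by a prominence criterion expressed as a fraction of the trace
interquartile range (default 0.25, making the segmentation invariant to
affine rescaling of the input) and a minimum half-cycle duration
(default 0.5 s; no plausible human breath is faster).  A light internal
pre-smoothing (0.3 s) removes sample-scale noise extrema before
segmentation; it is an order of magnitude shorter than any half-cycle.
Cycles are counted by inhalation onsets.  When both a chest and an
abdominal belt are recorded, the channel with more detected cycles is
kept (thoracic breathing moves the abdomen less, and vice versa); ties
keep the chest belt.

The pre-report analysis asks whether the instantaneous respiratory
phase at `report - k` seconds deviates from chance.  Chance is
participant-specific: the fraction of inhalation among 10 000 uniform
draws (with replacement - immaterial at this count) from the
participant's entire phase sequence.  Because the tested quantity is a
per-participant rate against a per-participant baseline, the group test
is a one-sample t test on the differences (rate minus own baseline),
which is exchangeable under the null; Cohen's d is the mean difference
over its standard deviation.  The offset convention is instantaneous:
"k s before the report" means the single sample at `report - k`.

## Cardiac chain

ECG is band-passed at 3-30 Hz (zero-phase, forward-backward
Butterworth), which suppresses baseline wander and T waves while
keeping the QRS complex.  R peaks are picked above an adaptive
threshold (a fraction, default 0.45, of the local signal maximum over a
2-s neighborhood, computed block-wise), with a 250-ms refractory period
and polarity normalization so inverted electrode placements detect
identically.  Manual beat inspection is replaced by quality flags:
intervals deviating more than 30% from the local median RR are flagged
for review rather than silently dropped, and a physiological gate
(0.25-3 s) flags implausible intervals.

RR intervals are labeled three ways, none of which mutates the
intervals: by attentional state (an interval belongs to a state when
its onset beat lies inside the epoch), by the second before the report
(ceiling rule on `report - beat`, so a beat 0.5 s before the report is
"1 s" and a beat exactly on a bin edge belongs to that bin), and by the
pre-report respiratory window (0-2 s before the report is the
inhalation-dominant period, 2-4 s the exhalation-dominant period; these
are fixed time-window proxy labels tied to the report-locked breathing
pattern, not the instantaneous phase).

## Heartbeat-evoked potentials

EEG preprocessing is deliberately minimal: integer-factor downsampling
to 250 Hz behind an anti-aliasing low-pass, a zero-phase 0.5-50 Hz
band-pass (separate high- and low-pass sections, because a single
narrow-edge band-pass of this ratio is numerically fragile),
power-line removal by regressing out a sinusoid at the line frequency,
and an average reference.  Artifact subspace methods (ICA and related
component rejection) are intentionally out of scope: the synthetic
recordings carry no ocular or myogenic artifacts, so nothing here
stands in for them.

HEP epochs span -200 to 600 ms around each detected R peak; epochs
crossing the recording edges are dropped, and each trial carries the
attentional state (and, when requested, the respiratory window) of its
beat.  Participants with fewer than ten MW reports are excluded - too
few beats fall into tagged windows for a stable evoked average.

Baseline handling is regression-based, never subtraction-based: the
baseline window (-200 to -75 ms, which avoids the R-peak artifact)
contains systematic cardiac components (P wave, Q onset, drift), and
subtracting it would push those into the post-peak window.  Instead,
per channel and time point a linear model
`amplitude ~ baseline_mean * condition` is fit across trials with
sum-to-zero condition coding (the intercept is then the grand mean),
and only the fitted contribution of the baseline mean and its
interaction with condition is removed.  Condition main effects survive
residualization, which is what the later contrasts test.  A constant
baseline (zero variance) drops the covariate with a message; a
rank-deficient design drops the interaction.  The model is fit per
participant; group statistics use per-participant cell averages.

## Time-frequency analysis

Spectral power comes from complex Morlet wavelets on a 2-40 Hz grid
with the number of cycles increasing linearly from 3 at 2 Hz; the slope
is configurable (default 0.5 cycles/Hz, i.e. 22 cycles at 40 Hz), since
only the intercept of the rule is fixed by convention.  Power is the
squared magnitude of the convolution, in linear units by default.
Samples within one wavelet half-length (3.5 Gaussian SDs) of an epoch
edge are excluded from every summary, so no output uses
edge-contaminated values.

Two summaries feed the statistics: (1) time-averaged power per state
epoch, channel and frequency - each epoch is treated as one stable
cognitive state - with trial-level values retained for the permutation
test; and (2) the continuous band-power course from 9.4 to 0.5 s before
each report (the window is trimmed at both ends by design: wavelet edge
effects at the far end, report-related artifacts at the near end),
sampled on a uniform grid and averaged over a participant's reports.
The grid step is configurable (default 0.1 s); the change-point model
below inherits it.

## Cluster-based permutation tests

Pointwise dependent-samples t statistics are computed per channel and
grid point, thresholded at two-tailed p < .05
(`|t| > qt(0.975, n - 1)`), and suprathreshold points of equal sign are
joined into clusters when they share a channel and are adjacent along
the axis, or share an axis position on neighboring channels.  Channel
neighborhoods come from 2-D montage distances (threshold 1.6 times the
median nearest-neighbor distance by default, configurable).  The
cluster statistic is the summed t.  The null distribution is the
maximum absolute cluster statistic over permutations; for a paired
design, permuting condition labels within participant is exactly a
random sign flip of each participant's difference, which is how it is
implemented.  Monte-Carlo p values use the add-one rule
`(1 + #(null >= |observed|)) / (1 + n_perm)`, so no p is ever zero, and
a cluster is significant at p < .025 per tail (a two-sided test).  The
permutation inner loop runs compiled; the exported `clusterize()` is
the reference implementation, and the tests hold the two to exact
agreement alongside a brute-force connected-component oracle.

Under-the-hood note: with n participants only `2^n` distinct sign
flips exist; when fewer than the requested permutations, the test warns
and samples with replacement.

## The dual-trend change-point model

The band-power course `Y[n, t]` (participant n, step t) is modeled as
Gaussian around a latent course: a participant-specific initial level
plus a trend shared across participants.  Two trend increment series
exist, pre and post; the level accumulates pre increments before the
discrete change point tau and post increments from tau onward, starting
from the value the pre series has reached at the change point.  The
latent course is therefore continuous and tau marks a trend break.

Priors: trend series are Gaussian random walks with innovation scales
sig_dpre, sig_dpost ~ half-Cauchy(0, 2.5); observation noise is
per-participant sig_y[n] ~ half-Cauchy(0, 5); initial trend values are
Normal(0, 1); participant levels have a vague Normal prior (mean = the
row mean, SD = 10 times the row SD); tau is uniform over interior
steps 2..T-1.

**Anchoring decision.**  The printed recursions admit two readings:
both latent series sharing their value at t = 1 (the observed course
then jumps at tau by the accumulated difference of the two trends), or
the post series starting from the pre series' value at the change point
(the course is continuous with a slope break).  Under the first
reading a continuous course - which is what band power before a report
looks like, and what the bundled generator produces - leaves tau
unidentified: the posterior piles at the window edge, as an exact
quadrature over the scale priors confirms.  The package therefore
implements the continuous reading, under which "two straight lines
with a slope break" is the zero-innovation limit and tau is identified
by the break.

**Sampler.**  Conditional on tau and the scales the model is
linear-Gaussian, and the bundled sampler exploits that: (1) tau moves
by Metropolis - plus a periodic exact categorical draw over all
candidates - under the *collapsed* marginal likelihood with levels and
trends integrated out analytically, which avoids the mode-sticking of
a tau-given-trends draw; (2) the trend scales also move under the
collapsed marginal (conditioning on the drawn trend series would
recreate the classic scale/latent funnel), with the random-walk prior
normalization included in the ratio; (3) a global multiplicative move
rescales all observation-noise parameters under the collapsed
marginal, so a badly scaled starting point relaxes quickly; (4) the
levels and both trend series are then redrawn jointly from their exact
multivariate normal conditional; (5) per-participant noise takes
log-scale Metropolis steps with burn-in-only adaptation (target
acceptance 0.44).  Chains start from jittered moment estimates; the
observation-noise initializer is `sd(diff(row))/sqrt(2)`, which tracks
the noise rather than the trend.  The per-candidate conditional
log-likelihoods whose log-sum-exp is the marginalized likelihood are
exposed (`cp_marg_loglik()`) and tested against brute-force per-tau
evaluation; the reported change-point mass is Rao-Blackwellized from
those same quantities.

The default regime is 4 chains of 6000 iterations, the first 1000
discarded as burn-in and the rest thinned by 2 - 2500 retained draws
per chain, 10 000 in total (`retained_draws()` does the accounting).
Reduced budgets are used in tests and the acceptance script; the fits
reported there use 4 chains of 2000 iterations (500 burn-in, thin 2) on
10 series of 50 steps, which converges with split-chain R-hat near
1.005 against the conventional 1.1 criterion.  Summaries report tau as
posterior mean, central 95% credible interval and mode, converted to
seconds before the report as `t0_offset - tau * step_dt`; the pre- and
post-trend means (each draw averages its increment series on its own
side of that draw's change point); and the difference pre minus post,
whose 95% interval lying entirely above zero is the "decrease after
the change point" verdict.

**Scaling.**  `cp_data_from_courses()` divides each participant's
course by its own mean (relative power).  The scale priors are fixed
numbers, so the data's units decide how permissive they are; relative
power puts courses from different heads on the common scale those
priors expect.

## What the synthetic generator emulates - and what it does not

`simulate_recording()` produces one session per call: respiration with
slow rate variability, configurable inhale fraction, linear plus slow
sinusoidal drift and additive noise; ECG as a stylized QRS template
(Gaussian lobes, maximum exactly at the nominal beat time) placed where
the integrated instantaneous rate crosses whole beats, the rate being
base heart rate plus respiratory sinus arrhythmia (faster during
inhalation) plus an event-locked offset profile in the seconds before
each report; EEG as 1/f background plus alpha (10 Hz) and beta (20 Hz)
oscillations whose band power follows a two-segment linear trend with a
known change point before each report (slopes in square-microvolts per
second), plus a heartbeat-locked late deflection (Gaussian bump
centered 480 ms after the R peak, support roughly 380-580 ms) on
posterior channels whose amplitude is set by the attentional state of
the beat; and an event table with tones (inter-stimulus interval
uniform in 1.2-2 s), state-dependent reaction-time noise, reports
separated by a minimum gap, resumptions, and a heartbeat-counting trial
table.  Everything derives from one master seed through per-modality
sub-seeds, so a fixed configuration is byte-identical across runs and
adding one modality never perturbs another.

Defaults encode the study conditions the pipeline is meant to detect:
slower breathing when attending the breath (11 vs 15 cycles/min),
alpha/beta power declining after a change point 4.7 / 3.5 s before the
report, a smaller heartbeat-locked deflection in the aware state than
in MW, and a heart-rate increase in the final second before the report.
Magnitudes in physical units are free parameters - the source
literature reports none - chosen so that the injected effects are
clearly expressed at session lengths of a few minutes.

Not emulated: ocular/myogenic artifacts, electrode pops, volume
conduction or any biophysical forward model, non-stationary noise, and
probe-caught designs.  Passing tests on this generator therefore show
that the pipeline recovers known effects from clean, correctly
synchronized signals; they do not show robustness to the artifact
structure of real recordings.

## Numerical choices and known limitations

- Moving averages use valid-window (partial) edges everywhere; no
  padding values are invented.
- The band-pass filters are run forward-backward (zero phase); the
  0.5-Hz high-pass is order 2 (order 4 at that edge ratio is unstable
  in double precision), the low-pass order 4.
- Monte-Carlo p values are add-one corrected; pointwise thresholds use
  the exact t quantile for the realized n.
- Change-point steps map to seconds as `t0_offset - step * step_dt`,
  with `t0_offset` the time-before-report of step 0 (one step before
  the first sample); with the default 9.4-0.5 s window at 0.1-s steps,
  step 47 is 4.7 s before the report.
- **Resolution limit of change-point recovery through the EEG chain.**
  The Morlet smear (about 0.4 s at 8-13 Hz under the default cycle
  rule) rounds any power kink.  When the per-participant course noise
  is small relative to the slope break - many reports per participant,
  moderate EEG noise - the posterior concentrates at the true change
  point (the test suite demonstrates mean recovery within 0.5 s using
  20 participants with 20 reports each at 0.5-s steps).  With few
  reports or fine steps, the posterior is honestly bimodal, with an
  Occam mode at the window edge where a single flexible trend explains
  the whole course; this is a property of the model class, not of the
  sampler, and is confirmed by exact quadrature over the scale priors.
- Under equal pre/post trends the per-tau conditional likelihood is
  exactly flat, but the marginal tau posterior is mildly non-uniform
  (a few log units of Occam preference toward early candidates);
  "diffuse under the null" holds in the sense of several steps of
  posterior spread, not exact uniformity.
- The half-Cauchy scales are fixed numbers; analyses should feed the
  model relative (mean-normalized) power, as the pipeline does, or
  re-examine the prior scales.
- The respiration phase detector assumes a roughly oscillatory belt
  signal; apneas or belt slips produce flagged, not corrected, output.
- R-peak detection assumes QRS-dominant polarity after normalization;
  heavily distorted ECG may need threshold tuning via the exposed
  parameters.

## Problem sizes used by the tests and acceptance script

Unit and property tests run on recordings of 40-220 s with 5-20
reports, permutation tests with 200 null datasets of 20 participants on
a 10 x 50 grid, and change-point fits on 10 series of 50 steps (2-4
chains, 800-2000 iterations).  The full pipeline smoke test simulates 4
participants x 2 conditions x 150 s and completes all nine stages well
under its 15-minute bound on one CPU.  These sizes are the package's
defaults for its own verification; scaling any of them up is a matter
of configuration, not code.
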