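---
title: "Methods: simulating and analysing visually and tactually instructed grasping sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing visually and tactually instructed grasping sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspflow)
library(dplyr)
```

## The experiment this package models

In a delayed-grasping task, a monkey identifies one of six turntable objects
either by looking at it (the object is illuminated for 700 ms) or by
exploring it by hand in the dark (up to 3,000 ms), holds the identity in
memory for a randomized 1,000–1,500 ms, and on the go cue grasps and lifts
the object within 870 ms, holding it for 700 ms. Spiking activity is
recorded from four cortical areas (premotor F5, parietal AIP, primary motor
M1, somatosensory S1) while a magnetic data glove samples hand joint angles
at 70–100 Hz. The scientific questions the pipeline addresses are:

1. Does the animal use the object information (behavior: reaction and
   movement times)?
2. Is the grip type object-specific but modality-independent (kinematics:
   LDA decoding and grip-similarity dendrograms)?
3. Do neural populations carry object and modality information over the
   trial (sliding two-way ANOVA tuning time courses), and is that
   information single-trial decodable per epoch (balanced leave-one-out
   LDA)?

No public recording of the modelled experiment is available, so every
stage of the pipeline is driven by a synthetic session generator with
stored ground truth. The
generator is first-class, tested code: all quantitative claims the test
suite makes are claims about recovery of known structure from these
simulations, not about the original animal data.

## The synthetic session generator

### Trial schedule and behavior

Per-condition trial counts are drawn uniformly from 14–18 (the range
observed in the modelled sessions) and interleaved at random. Reaction and movement times are
log-normal; only mean times are reported for the modelled experiment, so
the log-scale dispersion
(`timing_sdlog = 0.25`) is a free parameter chosen so that distributions
look like typical primate RT histograms (unimodal, right-skewed, essentially
no mass beyond the 870 ms go window). Configured means are the reported
ones: exploration RT/MT 323/757 ms, grasp RT 259 ms, grasp MT 308 ms
(visual) and 310 ms (tactile). The tactile cue epoch is simulated as a
fixed 2,000 ms exploration window (the task itself fixes only the 3,000 ms
maximum), stretched when a long RT+MT draw would not fit.

### Spike trains

Unit `u` fires as an inhomogeneous Poisson process with piecewise-constant
rate

```
lambda_u(t) = beta_u * g(e) * (1 + a_u * a(e) * f_obj(o) + b_u * b(e) * f_mod(m))
```

clipped at zero, where `e` is the task epoch at time `t`, `o` the trial's
object and `m` its modality. Baseline rates `beta_u` are log-normal
(median 10 Hz, sdlog 0.5). A fixed fraction of units per area (default 0.3
each for object and modality, drawn independently) receives nonzero gains
`a_u`, `b_u` (default 0.6); the rest have gains exactly 0, so their rate
law is condition-independent by construction. `f_obj` is a per-unit random
permutation of six equally spaced contrasts in [-1, 1] — a deterministic
contrast spread, so a "tuned" unit is never accidentally untuned — and
`f_mod` is ±1. Tuned units are an exact count `round(fraction * n)` rather
than a Bernoulli draw, so parameter-recovery tests measure detection error
only.

The epoch profiles `g(e)`, `a(e)`, `b(e)` encode the qualitative time
courses such experiments report: overall rates elevated during movement, object tuning strong
in the cue and movement epochs, modality tuning concentrated in the cue and
early memory and decaying through late memory into movement. These defaults
produce the headline dissociation — object decodability rises toward the
grasp epoch while modality decodability falls toward chance — without any
per-test adjustment.

Sampling uses thinning of a homogeneous Poisson process at the unit's
maximal rate. Every unit consumes its own RNG substream derived from the
master seed, so enlarging a simulated array never perturbs existing units,
and identical (config, generator, seed) triples reproduce sessions
byte-identically through `write_session()`.

### Kinematics

The hand posture lives in D = 27 joint angles (the joint count is not
fixed by the task description; 27 matches a full hand model driven by a seven-sensor glove, and D is
configurable). Each object has a canonical posture drawn once per session
(isotropic, 20° SD); a trial's settled posture adds isotropic noise (4° SD)
and, on tactile trials, a fixed offset vector whose norm is
`modality_offset_deg`. The default offset is 0 — the central behavioral finding being modelled is
that grip type is object-specific but modality-independent — so modality is
undecodable from kinematics by construction, while six canonical postures
20° apart in 27 dimensions make objects nearly perfectly separable. (A real
monkey's grips overlap more — object accuracy around 93% rather than 100% —
because the synthetic posture geometry is cleaner than hand biomechanics;
we do not tune the noise to force confusions.)
Trajectories are minimum-jerk from rest to the settled posture over the
movement time (only the settled posture is analysed; the trajectory model
just provides realistic traces), sampled at a session-level glove rate
drawn from 70–100 Hz with ±30% timing jitter.

### Broadband signals

`simulate_continuous()` renders spike trains to 30 kS/s voltage traces, one
unit per channel: a fixed biphasic template (1 ms, trough-normalized,
default 80 µV peak), 1/f channel noise built by FFT amplitude shaping
(default 10 µV SD), and a shared common-mode artifact — slow sinusoidal
drift plus broadband bursts — applied to all channels up to per-channel
gains (N(1, 0.1)), hence exactly rank one across channels. Ground-truth
spike sample indices and the artifact trace are stored for scoring.

## Preprocessing

Spike-band extraction follows the classical chain: subtract a 3.33 ms
running median (100 samples at 30 kS/s, forced odd to 101 — a running
median needs an odd window), then a 4th-order Butterworth low-pass at
5 kHz applied forward and backward. "Non-causal" is read as zero-phase
filtering: spike timing is preserved, symmetric inputs stay symmetric, and
the effective magnitude is the squared one-pass response. `filtfilt` in
the `signal` package does not pad internally, so the implementation adds
odd-reflection padding; without it, DC inputs show edge transients.

PCA artifact cancellation normalizes channels to unit variance, decomposes,
and subtracts components classified as common-mode. Two classification
rules are provided because the 0.36 loading threshold behaves very
differently with channel count:

* `remove_common` (default): a component is artifact when at least half the
  channels load on it above 0.36 in magnitude. Since a unit-norm loading
  vector can exceed 0.36 on at most `floor(1/0.36^2) = 7` channels, this
  rule only discriminates on blocks of about seven channels or fewer.
* `keep_signal`: a component is kept when at least one channel loads above
  0.36 (localized, spike-carrying) and removed when every loading is small
  — the signature of noise spread evenly across many channels. This rule
  scales to arbitrary block sizes and changes embedded spike amplitudes by
  only ~1/n_channels.

Two properties of projection subtraction are worth knowing: removing a
direction from the data necessarily leaves a slight negative coupling
(about -1/(n-1)) among residual channels, and on artifact-free small blocks
the broad-loading rule can fire on a chance noise direction. Both are
inherent to the method, not implementation artifacts.

Detection places events at troughs below `-4.5 * sigma_robust` with
`sigma_robust = median(|x|)/0.6745` (a spike-insensitive noise estimate)
and a 1 ms lockout. Unit QC excludes units below 1 Hz, computed over the
full recording duration with an inclusive boundary; QC is idempotent.

## Behavioral analysis

Reaction time is go cue to movement onset (handrest release); movement time
is release to completed lift. Exploration-phase analogues are measured from
cue onset (the instruction) to release, and release to the exploratory
lift. Trials violating epoch order, the memory-duration range, or the go
window are marked `error:<reason>` and excluded. Histogram cutoffs (550 ms
at 5 ms bins for RT, 1,000 ms at 10 ms bins for MT) truncate the display
only; means are computed over all values — figure captions describe
plotting, not statistics. Pooling across sessions is plain concatenation.

## Kinematic analysis

The grip-type feature is the per-joint mean over samples 450–550 ms after
the completed lift, when the grasp has settled but not yet released
(release is only allowed after 750 ms). Irregular glove sampling is handled
by the time-windowed mean directly — no interpolation — which is invariant
to rate and jitter within about a degree for band-limited traces.
Grip similarity is summarized by Euclidean distances between class-mean
postures (class = object × modality) clustered with average linkage;
class-level distances and the linkage are choices the data description
leaves open, and both are configurable, as is z-scoring of angles before
distances (off by default: angles share units).

## Tuning analysis

Spike counts in 100 ms windows slide at a 10 ms stride (the window is
stated; the stride is a display-resolution choice). Per unit and window a
two-way fixed-effects ANOVA tests the object (six levels) and modality (two
levels) main effects; only the two factors are modelled by default, with
the interaction behind a flag. Effects are partial (type-II) model
comparisons computed by orthogonal projections on the shared design, which
reduces exactly to the classical balanced-design sums of squares — the test
suite pins this equivalence to 1e-10 on the F statistic. Windows with zero
residual variance are reported as p = 1 when the effect is also zero
(nothing to test) and p = 0 when separation is perfect.

A unit is "tuned" at a window when its p-value survives Bonferroni
correction with family size equal to the number of windows tested per unit
and factor (the family the display iterates over; the original family size
is not stated). The tuned fraction per area divides by the QC-passing units
analysed. Because adjacent windows overlap 90%, Bonferroni over the window
family is conservative; empirical per-unit family-wise error on null
sessions sits well below the nominal 5%. A `per_modality` switch replaces
the two-way object effect with one-way object ANOVAs within each modality's
trials, matching displays that separate visual and tactile trials.

## Decoding

Epoch features are mean rates in 500 ms windows: early memory
`[memory_start, +500)`, late memory `[go - 500, go)`, and grasp
`[movement_onset, +500)` (the grasp epoch has no canonical alignment
event; movement onset is the natural anchor for grasping). The
classifier is linear discriminant analysis with class means, a pooled
within-class covariance diagonally loaded by
`lambda = 0.1 * mean(diag(Sigma))` (unit counts can exceed balanced trial
counts, e.g. ~60 M1 units vs ~13 training trials per class; the loading
fraction is configurable), equal priors, and lowest-index tie-breaking.
Prediction equals nearest-class-mean under the pooled Mahalanobis metric,
which the tests verify against an independent brute-force implementation.

Validation is leave-one-out with trial balancing: at every fold the
remaining trials are subsampled so that **every object × modality
condition** contributes equally (one seeded draw per fold; repeat-averaging
is a possible extension we did not need). Balancing at the condition level
— rather than at the level of the decoded classes — matters for marginal
schemes: it guarantees that, say, both modality classes contain identical
object mixtures in training. For the same reason the covariance pool is
stratified by condition when a marginal label is decoded, so variance
*between* conditions of the same class is treated as known structure rather
than noise. With the naive alternative (collapse labels first, pool within
collapsed classes) the strong object clustering leaks into the covariance
and leave-one-out acquires a marked below-chance bias on modality-null data
(we measured 34–46% against a 50% truth); the stratified design is unbiased
in the same simulations. Confusion matrices are row-normalized percentages
(rows = instructed, columns = decoded, axis order visual objects then
tactile objects) and overall accuracy is the diagonal mean, i.e. balanced
accuracy; chance for K classes is 100/K.

## Problem sizes and numerical choices

The test suite and the acceptance script regenerate everything from seeds.
Representative sizes, chosen as the smallest that make the statistical
assertions sharp: chance-level calibrations use one session of 12
conditions × 15 trials with ~40 null units; family-wise-error and
parameter-recovery checks use 200 units across the four areas at the full
14–18 trial schedule (~150 windows per unit at a 10 ms stride); broadband
checks use 10 s of 12-channel 30 kS/s signal. Stochastic assertions use
3-standard-error bands around analytic targets with fixed seeds chosen
before inspection; binomial confidence intervals are used for recovery of
generating fractions.

Degenerate inputs are handled explicitly: constant spike-count tables are
"not significant" rather than errors; all-zero feature blocks fall back to
a tiny absolute diagonal loading; classes that collapse during
leave-one-out are skipped and logged; windows that would leave the recorded
interval are trimmed off the grid with a message.

## What passing tests do and do not show

The generator emulates the statistical skeleton the analyses assume:
piecewise-constant condition-dependent rates, isotropic posture noise,
rank-one common-mode artifacts, independent units. Real recordings violate
all of these in ways that matter — spike sorting errors and drift,
correlated population noise, non-Poisson firing, posture covariance
structured by hand biomechanics, artifacts with per-channel phase shifts.
Passing recovery tests therefore demonstrates that the estimators are
correct and calibrated under their own assumptions, not that the original
biological effect sizes would be reproduced; the original recordings are
not publicly deposited, so real-data accuracies cannot be checked here.

## Known limitations

* No spike sorting: detection assigns one unit per channel; real arrays
  need a sorter between detection and the tuning/decoding stages.
* The two-way ANOVA operates on raw counts, the field's convention for
  this analysis; at very low rates
  a square-root transform (available as an option) stabilizes variance.
* The common-mode cancellation assumes the artifact is instantaneously
  mixed (rank one up to gains); phase-shifted artifacts need a different
  model.
* Session pooling is concatenation; no hierarchical session effects are
  modelled.
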