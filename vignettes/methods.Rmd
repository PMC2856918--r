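---
title: "Detecting theta-coupled replay in working-memory maintenance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting theta-coupled replay: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thetareplay)
```

## The scientific problem

During a delayed match-to-sample task, the stimulus-specific cortical
activity pattern elicited while a picture is viewed can re-emerge
("replay") while the picture is held in working memory across a delay.
`thetareplay` implements a complete analysis chain for detecting such
replay in multichannel oscillatory recordings (M/EEG-style sensor arrays)
and for quantifying how tightly replay events are coupled to the phase of
the ongoing theta (4-8 Hz) rhythm, which is hypothesized to clock periodic
reactivation.

Because no raw recordings accompany this problem, the package treats the
analysis and a synthetic-data generator as one artifact: the generator
plants category-specific spectral patterns, theta oscillations, and replay
events with *known* timing and phase statistics, so every stage of the
chain can be validated by parameter recovery rather than by eyeballing.

## The reference design

One simulated study mirrors the reference task structure:

* 8 subjects; three task conditions (*control*, *nonconfigural*,
  *configural*) crossed with two picture categories (*indoor*, *outdoor*),
  20 trials per category per condition;
* 9 s epochs at 480 Hz: 1 s pre-stimulus baseline, 3 s sample
  presentation, 5 s maintenance, with the outer 1 s margins retained to
  absorb wavelet edge effects;
* 64 sensors on a unit grid (a 275-sensor helmet-like layout is available
  via `helmet_layout()`).

## The synthetic generator

`generate_subject()` builds each trial as the sum of four components:

1. **1/f background noise**, unit variance per sensor, synthesized by
   spectral shaping of white noise (`noise_exponent`, default 1).
2. **Slow cortical-state gain fluctuations**: the noise is multiplied by a
   lognormal field (log-sd `noise_gain_sd` = 0.5, band-limited below
   0.5 Hz, half the variance shared across sensors). This matters more
   than it may look: single-trial spectral amplitude in real recordings
   fluctuates strongly and coherently across frequencies, and it is
   precisely this variability that keeps single-trial classifier outputs
   variable when no stimulus pattern is present. With stationary noise,
   a trained network maps the featureless maintenance state to one fixed
   saturated output and produces massive spurious "reactivations"; with
   realistic state fluctuations the false-detection floor collapses to the
   binomial prediction.
3. **A coherent theta oscillation** (6 Hz, amplitude 2 x noise sd) on a
   12-sensor cluster (`default_theta_cluster()`), with a subject-specific
   phase offset common to all trials. Sensors outside the cluster carry no
   sinusoidal theta, so their 6 Hz phase estimates decohere within a
   trial - this is what makes phase-locking sensor-specific, since a
   per-trial PLV is invariant to any constant phase offset.
4. **Category patterns and replay bursts**: each (condition, category)
   cell receives a distinct spectral pattern - four carrier frequencies
   drawn from a cell-specific pool inside the 13-79 Hz classifier band,
   random amplitudes and phases, projected onto a random 4 x 4 sensor
   block. The pattern is added during the sample window at
   `pattern_snr` = 2 (relative to noise sd), rising 200 ms after picture
   onset with a 100 ms ramp, since category-selective responses emerge a
   couple of hundred milliseconds post-stimulus; nothing category-specific
   exists before onset, which is what makes the baseline (-36 ms)
   classifier a genuine negative control. During maintenance the same
   pattern is re-injected as replay bursts (250 ms, tapered-cosine
   envelope) whose theta phases follow a von Mises law with preferred
   phase `coupling_mu` and concentration `coupling_kappa`.

### Why replay is trial-coherent

Replay event trains are drawn once per (subject, condition, category) cell
and expressed in every trial of that cell. The detection rule of the
decoder stage declares a reactivation only when **all 20** trials of a
category produce confident correct outputs at the same time point (see
below). If each trial had independent Poisson replay, the probability that
20 trials all carry a burst at one time point would be `coverage^20`,
i.e. essentially zero at any plausible rate, and the published rule would
have no power under the generator. Trial-coherent replay - a
subject-level reactivation process expressed in each trial - is the
regime in which the rule is informative. Per-trial event counts still
follow Poisson(`replay_rate` x 5 s), and events are placed on theta
cycles at the time where the planted oscillation attains the drawn phase,
so the generator's `coupling_kappa` is exactly the quantity the PLV stage
estimates.

Default rates are 0 (control), 0.8/s (nonconfigural), and 1.2/s
(configural); default concentrations 0, 4, 8. These are the package's
reference effect sizes: strong enough that ordering and specificity
recovery are expected at 8 subjects, zero in control by design.

## Time-frequency analysis

Spectral amplitude is estimated by continuous wavelet transform with
complex Morlet wavelets at a fixed ratio f/sigma_f = 7, on a grid of 1 Hz
steps over 2-20 Hz and 2 Hz steps over 21-79 Hz (49 bins; the 38 bins in
13-79 Hz form the classifier feature band). Amplitude is the modulus of
the complex coefficient; normalization is such that a unit-amplitude
sinusoid yields unit modulus (phase is scale-invariant, so the choice is
immaterial for coupling). Implementation is FFT-based circular
convolution; the 1 s epoch margins absorb the wrap-around, and an error is
raised when an epoch is shorter than the wavelet support at the lowest
frequency.

Numerical choices worth knowing:

* When amplitude is requested at selected time points only
  (`cwt_amplitude(..., times_ms = ...)`, which is how the pipeline keeps
  cohorts in memory), each frequency's coefficient spectrum - a narrow
  Gaussian band - is inverted at a decimated length covering at least
  24 sigma_f of bandwidth and the smooth amplitude envelope is linearly
  interpolated. Against the exact full-length transform the error is
  under ~2% at sharp transients and numerically zero for stationary
  content.
* The 480 -> 250 Hz conversion (`downsample_tf()`) is linear
  interpolation onto a uniform 4 ms grid; 480/250 permits no integer
  decimation. Amplitude envelopes are already smoothed at the wavelet
  timescale (sigma_t >= 28 ms), for which linear interpolation at 4 ms
  spacing is accurate to well under 1%.
* Baseline normalization subtracts, per trial/sensor/frequency, the mean
  amplitude over -500 to -100 ms; it is idempotent.
* The zero-phase high-pass before phase estimation is a 4th-order
  Butterworth applied forward-backward (order and family configurable;
  only "zero-phase" is inherent to the method).
* Instantaneous theta phase is the argument of the Morlet coefficient at
  4, 5, and 6 Hz, reported on the 250 Hz grid by nearest native sample
  (at 6 Hz the 1 ms nearest-sample error is < 0.04 rad).

## Decoding and reactivation statistics

At each training time point (-36 ms, then 44-764 ms in 80 ms steps), a
two-tailed paired t test (p < 0.05) over the 20 indoor/outdoor trial
pairs selects discriminative (sensor, frequency) bins in 13-79 Hz;
pairing is by presentation index. A feedforward network (selected bins ->
20 logistic hidden units -> 2 logistic outputs, targets (1 0)/(0 1)) is
trained by conjugate gradients with restarts for exactly 20 iterations on
the sum of squared errors, from small uniform random weights with a
logged seed. Inputs are the raw baseline-normalized amplitudes: early
experiments with per-feature standardization showed that centring places
the featureless maintenance state in a far corner of input space where
the network saturates arbitrarily - raw amplitudes keep that state near
the origin and its outputs variable.

Encoding-period accuracy is estimated by leave-one-out cross-validation
with feature selection re-run inside every fold on the remaining trials
only; the held-out trial never touches selection or weights (verified by
a mutation test). Maintenance activity is tested at 250 evenly spaced
points spanning 3250-7750 ms (the 4.5 s remaining after trimming 250 ms
at each end; "250 consecutive points" cannot tile 4.5 s at 250 Hz, so
even spacing of ~18 ms is used and configurable). A trial is *correct* at
a point iff the output unit of its true category exceeds 0.95; trials
with both outputs above 0.95 are flagged ambiguous and not counted.

With C correct of n = 20 trials at chance r = 0.5, the one-tailed
normal-approximation p value (no continuity correction) is compared with
the Bonferroni-corrected threshold 0.05/(250 x 11) = 1.8e-5; the only
attainable significant count is 20/20, under both the approximation and
the exact binomial (the package carries the exact method as an oracle).
Reactivation counts are totalled per subject/condition/category over the
ten post-onset classifiers, and condition contrasts use paired one-tailed
t tests over subjects. Cross-condition testing applies classifiers
trained in one condition to the maintenance data of another; with
condition-specific pattern codes in the generator, within-condition
counts should exceed cross-condition counts.

## Phase coupling statistics

Reactivation events (the union over classifiers trained 44-764 ms, with
duplicate (trial, time) detections collapsed - one pattern occurrence
should count once) are assigned the instantaneous theta phase at the
nearest 250 Hz sample, per sensor. Per trial j, the phase-locking value
is the modulus of the mean unit phasor of its event phases; trials with
fewer than 2 events are excluded (a single event gives PLV 1 trivially)
and logged. PLVs are normalized with the arcsine transform
z = asin(2 PLV - 1). For N uniform phases E[PLV] ~ sqrt(pi)/2 / sqrt(N):
the suite checks this small-N bias explicitly so it is never mistaken for
coupling.

Condition contrasts average z within subject x sensor x condition and
treat subjects as paired units (trial-level pairing is ill-defined when
trial event counts differ; subject-level pairing is the default and the
documented choice). Multiplicity over sensors is controlled by a
cluster-based permutation test: sensors with p < 0.05 form connected
clusters under the layout adjacency (grid: rook+bishop neighbours within
1.5 x spacing; helmet: symmetrized k = 6 nearest neighbours), candidate
clusters need at least 8 members, cluster mass is the summed |t|, and the
null distribution of maximal masses comes from within-subject sign flips
of the condition difference.

The within-subject permutation test builds its null by circularly
shifting each trial's event train against its phase series by an
independent uniform offset, which preserves the inter-event (temporal
correlation) structure exactly. Its statistic is the arcsine-z of the
PLV over all events pooled across trials, not the mean of per-trial
PLVs: a circular shift rotates every phase within a trial by one
constant, so per-trial PLV magnitudes are invariant under the shift null
whenever theta is near-sinusoidal, and only a cross-trial consistency
statistic gives this null discriminating power.

Coupling-behavior correlation is Pearson's r, per sensor, between
subjects' trial-mean z and behavioral accuracy, with sensors flagged at
r > 0.7 and p < 0.05 (two-tailed) and flagged sets reported only when at
least 8 are mutually adjacent. The generator can tie accuracy linearly to
each subject's coupling concentration (`kappa_spread`, `behav_slope`) for
correlation-recovery tests; with the default slope of zero the map is
expected to be empty.

## What the simulations do and do not show

The generator emulates the *structure* that the analysis depends on:
spectrally specific category codes, theta-clocked trial-coherent replay,
sensor-cluster topography, 1/f background with realistic state
fluctuations, and a behavioral covariate. It does not emulate cortical
source geometry, evoked transients, artifacts (blinks, cardiac), phase
resets, inter-subject topographic variability, or non-sinusoidal theta.
Passing parameter-recovery tests therefore certifies the *chain* -
that the statistics recover what was planted under the stated
assumptions - not that real recordings would yield any particular
result.

## Problem sizes and numerical tolerances used by the test suite

* The acceptance cohort is the full reference design (8 subjects,
  20+20 trials x 3 conditions, 64 sensors); it is analyzed once and
  shared by the chance-level, ordering, and specificity checks.
* The baseline-decoding check accepts a cohort-mean LOOCV accuracy within
  0.05 of 0.5 - the binomial 95% band for 960 folds widened for the
  correlation between folds sharing 38 of 39 training trials.
* Parameter recovery runs single subjects at replay rate 1.6/s over the
  kappa ladder {0, 1, 4, 20}; preferred-phase recovery is required within
  0.2 rad at kappa = 20.
* Error-rate checks run 200 replicate null cohorts at the coupling-model
  level (uniform event phases feeding PLV -> contrast -> cluster
  permutation at 500 permutations) rather than re-synthesizing raw
  signals per replicate: the controlled quantity - the family-wise error
  of the cluster test and the type-I rate of feature selection - lives
  entirely at that level.
* The von Mises sampler is the Best-Fisher rejection algorithm; circular
  summaries (mean direction, resultant length) are computed from unit
  phasors, and a Rayleigh-test oracle guards the kappa = 0 case.

## Known limitations

* Theta is stimulus-locked (common phase trajectory across trials within
  a subject); ongoing drifting theta would leave PLV magnitudes intact
  but break preferred-phase recovery across trials.
* The 20/20 detection rule makes the pipeline's sensitivity an
  all-or-nothing function of per-trial classifier confidence; moderate
  coverage or lower SNR degrades counts sharply rather than gracefully.
* Linear interpolation (rate conversion, zoomed CWT) trades a ~1-2%
  transient amplitude error for large memory and time savings; exact
  full-grid transforms remain available via `cwt_amplitude()` defaults.
* The normal-approximation p value overestimates the extreme binomial
  tail (at C = 20 of 20 by a factor ~4); the decision it feeds is
  nevertheless identical to the exact test's for every count, which is
  what the detection rule needs.
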