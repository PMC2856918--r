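# thetareplay

Detection of stimulus-specific replay during working-memory maintenance in
multichannel oscillatory recordings, and quantification of its coupling to
the theta rhythm — together with a synthetic-data generator that plants
ground-truth replay so the whole analysis chain is verifiable by parameter
recovery.

## Who this is for

Researchers analyzing M/EEG-style delayed match-to-sample experiments who
want a tested, reproducible implementation of the classic
decoding-plus-phase-coupling pipeline:

1. **Time-frequency analysis** — complex Morlet CWT with a fixed ratio
   f/σ_f = 7 on a 2–79 Hz grid (49 bins), single-trial baseline
   normalization (−500 to −100 ms), downsampling to 250 Hz.
2. **Time-resolved multivariate pattern classification** — per training
   time point, paired-t feature selection (p < 0.05, 13–79 Hz bins), a
   feedforward network (features → 20 hidden → 2 sigmoid outputs, targets
   (1 0)/(0 1)) trained by conjugate gradients for exactly 20 iterations;
   leave-one-out cross-validation during encoding; single-trial testing at
   250 points of the maintenance interval with a 0.95 output threshold.
3. **Reactivation statistics** — with C correct of n = 20 trials at chance
   r = 0.5, one-tailed binomial significance (normal approximation, exact
   oracle included) against the Bonferroni-corrected threshold
   0.05/(250 × 11) = 1.8 × 10⁻⁵, which only 20/20 attains; counting and
   paired one-tailed condition contrasts; cross-condition specificity.
4. **Theta phase coupling** — zero-phase 3 Hz high-pass, instantaneous
   phase at 4/5/6 Hz, per-trial phase-locking value
   PLV = |Σ exp(iφ)|/N with arcsine normalization z = asin(2·PLV − 1),
   sensor-wise paired contrasts with cluster-based permutation control
   (≥ 8 adjacent sensors), within-subject circular-shift nulls, and
   coupling–behavior Pearson correlation (r > 0.7, p < 0.05 flagging).

Everything runs on synthetic cohorts whose replay timing, theta phases
(von Mises with known μ, κ), spectral patterns, and behavioral accuracies
are known, so each stage is validated by recovering what was planted.

## Worked example

```r
library(thetareplay)

cfg <- pipeline_config(
  generator = list(n_subjects = 3, rng_seed = 11),
  seed = 11, verbose = FALSE)
report <- run_pipeline(cfg)
print(report)
```

```
<replay_report>
  seed 11; 3 subjects; corrected alpha 1.82e-05
  baseline LOOCV accuracy (mean): 0.478
  mean within-condition reactivation counts: control 0.0, nonconfigural 535.3, configural 577.7
  configural_vs_control: t = 4.00, one-tailed p = 0.02866
  nonconfigural_vs_control: t = 10.52, one-tailed p = 0.00446
  configural_vs_nonconfigural: t = 0.25, one-tailed p = 0.4116
  elapsed 310.8 s
```

Reading the output: the baseline (−36 ms) classifiers decode at chance
(0.478 ≈ 0.5), as they must, since the generator plants no pre-stimulus
category information. Control maintenance produces no reactivations (its
replay rate is 0), while both memory conditions produce hundreds of
significant 20/20 time points, significantly above control by paired
one-tailed t tests. The coupling stage then estimates each trial's
phase-locking of those reactivation events to 6 Hz theta and contrasts
conditions over sensors with cluster-permutation control.

Lower-level entry points (`generate_subject()`, `cwt_amplitude()`,
`select_features()`, `train_classifier()`, `loocv_accuracy()`,
`classify_maintenance()`, `detect_reactivations()`, `event_plv_table()`,
`cluster_permutation()`, `within_subject_permutation()`,
`behavior_correlation()`) expose every stage separately; the methods
vignette (`vignettes/methods.Rmd`) documents the models, defaults, and
numerical choices.

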