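# painfuse

Multimodal MRI feature fusion for predicting an individual's pain
sensitivity.

## The problem

A person's laser pain threshold — the stimulus energy (in Joules) at which
an ascending series of laser pulses is first rated 4 out of 10 — varies
widely between healthy people and matters clinically. Brain MRI carries
information about that variability in two modalities and two feature
families:

- resting-state fMRI: voxel-wise **ReHo** (regional homogeneity, Kendall's
  coefficient of concordance W of each voxel's time series with its 26
  neighbours) and ROI-pair **FC** (functional connectivity, Fisher-z
  Pearson correlation of ROI time courses);
- diffusion tensor imaging: voxel-wise **FA** (fractional anisotropy,
  FA = √½ · √[((λ₁−λ₂)² + (λ₂−λ₃)² + (λ₃−λ₁)²) / (λ₁²+λ₂²+λ₃²)] from the
  tensor eigenvalues) and ROI-pair **SC** (structural connectivity, the
  probability that a stochastic streamline seeded in region i reaches
  region j).

`painfuse` implements the full pipeline: temporal fMRI preprocessing
(initial-volume discard, Friston-24 motion regression with framewise-
displacement scrubbing via spike regressors, 0.01–0.1 Hz band-pass),
extraction of all four feature types, per-feature-type prediction of the
threshold by leave-one-individual-out cross-validation (LOOCV) with
fold-wise correlation-based feature selection (no statistic ever touches
the held-out subject), decision-level fusion (the fused prediction is the
unweighted mean of single-type model predictions), evaluation (PCC, MAE,
paired t-tests on absolute errors, and the Meng–Rosenthal–Rubin z-test for
dependent correlations sharing the true labels), and selection-frequency
stability analysis of which features are chosen in more than half of the
folds.

Because no imaging data are bundled, a first-class synthetic-data module
generates parcellations, BOLD volumes, motion traces, tensor fields,
feature tables and staircase-quantised thresholds (mean of two
measurements snapped up to the 0.25 J grid starting at 1 J; population
calibrated to ≈ 2.57 ± 0.53 J) with planted linear signal and a
controllable redundancy knob between modalities. Everything runs and is
tested end-to-end without any download.

## Worked example

The analysis scripts run the desk-scale study in sequence (each writes its
tables under `results/`):

```sh
Rscript analysis/01_simulate_study.R      # 210 subjects, 4 feature blocks
Rscript analysis/03_predict_models.R      # 9-model LOOCV suite
Rscript analysis/04_evaluate.R            # performance + 36 comparisons
Rscript analysis/05_stability.R           # common predictive features
Rscript analysis/02_image_pipeline_demo.R # full imaging pipeline, tiny cohort
```

Stage 3/4 output on the default study (210 subjects; 500-column regional
blocks; 90-ROI, 4005-column connectivity blocks; complementary planted
signal):

```
Prediction performance by feature set
  reho         MAE 0.413 +/- 0.285   PCC 0.497 (p = 1.8e-14)
  fc           MAE 0.482 +/- 0.372   PCC 0.169 (p = 0.0143)
  fa           MAE 0.458 +/- 0.337   PCC 0.315 (p = 3.22e-06)
  sc           MAE 0.459 +/- 0.368   PCC 0.259 (p = 0.000149)
  regional     MAE 0.383 +/- 0.284   PCC 0.595 (p = 1.74e-21)
  connectivity MAE 0.433 +/- 0.345   PCC 0.299 (p = 1.01e-05)
  fmri         MAE 0.403 +/- 0.303   PCC 0.499 (p = 1.23e-14)
  dti          MAE 0.421 +/- 0.309   PCC 0.422 (p = 1.83e-10)
  fused        MAE 0.392 +/- 0.286   PCC 0.686 (p = 1.65e-30)
Fused-vs-single dependent-correlation tests: 8 of 8 at p < 0.05
```

Reading this: each row is one model's out-of-fold accuracy — MAE is the
mean ± sd of per-subject absolute errors in Joules, PCC the correlation
between predicted and true thresholds across the 210 subjects. With
complementary signal the fused model (mean of the four single-type
predictions) clearly beats every constituent, and the dependent-correlation
test confirms each gain; connectivity models trail regional ones because
fold-wise selection over 4005 candidate columns admits more spurious
features. Stage 5 then reports that every planted feature is selected in
more than half of the folds in all four blocks (11–14 stable features per
block against 10 planted).

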