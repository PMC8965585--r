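---
title: "Predicting individual pain sensitivity from multimodal MRI features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting individual pain sensitivity from multimodal MRI features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Pain sensitivity varies enormously between healthy people, and a person's
laser pain threshold — the stimulus energy, in Joules, at which an ascending
series of laser pulses is first rated 4/10 — is a clinically meaningful
summary of that variability. Brain imaging offers two complementary windows
onto its neural basis: resting-state fMRI captures spontaneous functional
activity, diffusion tensor imaging (DTI) captures white-matter
microstructure. Within each modality one can extract *regional* features
(a value per voxel) and *connectivity* features (a value per region pair).
`painfuse` implements a complete pipeline that extracts all four feature
types — ReHo and functional connectivity (FC) from fMRI, fractional
anisotropy (FA) and structural connectivity (SC) from DTI — predicts each
individual's pain threshold by leave-one-individual-out cross-validation
(LOOCV) with fold-wise correlation-based feature selection, fuses the
single-feature-type models at the decision level, and asks whether fusion
beats any single feature type.

Because no public dataset accompanies this design, the package treats the
synthetic-data generator as a first-class module: every stage runs, and is
tested, on simulated cohorts whose statistical structure matches what the
real features would carry.

## Feature extraction

**fMRI preprocessing.** The temporal chain is fixed and test-asserted:
discard the first 10 volumes; regress out the Friston-24 motion expansion
(the 6 rigid-body parameters, their one-frame lags, and both sets of
squares) together with one spike regressor per scrubbed frame; band-pass
0.01–0.1 Hz with an ideal frequency-domain mask after demeaning. Scrubbing
uses Power-style framewise displacement, FD(t) = sum of absolute
translation increments plus 50 mm times the sum of absolute rotation
increments, with a strict > 0.2 mm rule (a frame at exactly 0.2 mm is
kept). Scrubbed frames are modelled as covariates rather than deleted so
the series stays contiguous for the filter. Spatial steps that require a
registration toolchain (realignment, normalisation, segmentation) are out
of scope: volumes are assumed co-registered to a common grid.

**ReHo.** For each in-mask voxel, Kendall's coefficient of concordance
W over the time series of the 3×3×3 neighbourhood (truncated to in-mask
members, K series): rank each series over time, let R_t be the rank sum at
time t, S = Σ_t (R_t − mean R)², and W = 12 S / (K²(n³ − n)) with n the
number of timepoints. Ties get average ranks; by default no tie-correction
term enters the denominator (the common toolbox convention; a
tie-corrected variant sits behind `tie_correct = TRUE`). Neighbourhoods
with fewer than `k_min = 4` members, or in which every series is constant,
get W = 0 (the latter with a warning). ReHo maps are smoothed (6 mm FWHM
Gaussian, mask-renormalised) and equalised by division by the in-mask mean
(z-standardisation available via `method = "zscore"`). W is computed before
smoothing; smoothing a concordance statistic rather than the raw series
follows the stated extraction order.

**FC.** ROI time courses are unweighted means over in-mask voxels; FC is
the Pearson correlation matrix of those courses, Fisher z-transformed with
r clipped at ±(1 − 1e−7) so z stays finite, diagonal stored as 0. The
strictly-lower triangle in row-major order gives the feature vector
(4005 features at 90 ROIs).

**FA.** FA = sqrt(½) · sqrt(((λ1−λ2)² + (λ2−λ3)² + (λ3−λ1)²)/(λ1²+λ2²+λ3²))
from the eigenvalues of each voxel's tensor; 0 for a spherical diffusion
ellipsoid, 1 in the degenerate single-axis limit. The implementation
diagonalises the reassembled 3×3 tensor; tests cross-check against the
equivalent mean-diffusivity form sqrt(3/2)·‖λ − λ̄‖/‖λ‖.

**SC.** Probabilistic tractography seeds a configurable number of
streamlines from every in-mask voxel of each ROI. Directions are sampled
around the local principal tensor axis with a von Mises–Fisher-like
concentration (κ → ∞ recovers deterministic tracking); the sign is chosen
to minimise turning, and tracking stops on mask exit, FA below `fa_stop`,
an angle violation, or `max_steps`. The connectivity probability from ROI
i to ROI j is the number of streamlines seeded in i whose path intersects
j divided by the total seeded in i — a binomial proportion, so every SC
property in the tests is phrased in binomial standard errors and holds at
any sample count (the full protocol uses 5000 per voxel; tests use 1–50).
Since single-tensor fields cannot represent crossing fibres, the sampler
perturbs the principal axis rather than an orientation-distribution
function; the probability definition is unchanged. The possibly
asymmetric matrix is symmetrised as (A + Aᵀ)/2 before vectorisation
(asymmetry is reported as an attribute), giving SC the same 4005-length
layout as FC.

Stopping defaults (fa_stop 0.15, 45° angle limit, step = half the smallest
voxel size, 500 steps) follow common tractography practice and live in
`tractography_params()`.

## Prediction

For each feature type, LOOCV over n subjects: in each fold the held-out
subject contributes nothing to feature selection (two-sided Pearson
correlation p < threshold against the training thresholds, constant
columns excluded), nothing to normalisation (per-feature z-score with
training mean/sd), and nothing to fitting. A fold that selects no features
predicts the training mean. The retained per-type settings are ReHo and FC
with linear-kernel SVR at p < 0.001, FA with RBF-kernel SVR at p < 0.01,
and SC with RBF-kernel SVR at p < 0.001; `model_selection_grid()` exposes
the algorithm × threshold screening that such settings come from, with the
documented caveat that picking the best cell on the same folds later
reported is optimistic model selection.

Hyperparameters are deliberately plain (SVR C = 1, ε = 0.1, RBF
γ = 1/(d·var(X)); PLSR components min(5, d, n−1); RF 500 trees) and sit in
config; SVR/RF/PLS internals are delegated to e1071, randomForest and
mixOmics — the bespoke content is the surrounding procedure.

The nine models are the four single-type models plus five fusions
(regional = ReHo+FA, connectivity = FC+SC, fMRI = ReHo+FC, DTI = FA+SC,
fused = all four), where fusion is *only* the unweighted mean of the
constituent single-type predictions — it never touches their selection or
fitting, and the tests assert the fused vector equals the elementwise mean
to 1e−12.

## Evaluation

Per model: Pearson correlation between out-of-fold predictions and true
thresholds (two-sided t-based p), and MAE with the sample standard
deviation of the absolute errors ("mean ± std"). Pairwise: a paired t-test
on absolute errors, and — because every model's accuracy correlation
shares the same true labels — the Meng–Rosenthal–Rubin z-test for
dependent correlations sharing one variable:

z = (z_A − z_B) · sqrt((n − 3) / (2(1 − r_AB) h)),
r̄² = (r_Ay² + r_By²)/2, f = min(1, (1 − r_AB)/(2(1 − r̄²))),
h = (1 − f·r̄²)/(1 − r̄²).

Two numerical findings worth recording. First, the test's unconditional
type-I rate is nominal in simulation (≈ 0.047 at α = 0.05, n = 210,
r_AB = 0.5, 2000 replicates). Second, on a *given* dataset its p-value can
differ from the exact conditional sign-flip permutation distribution by up
to ≈ 0.1 in the mid-range at n = 100 — the normal approximation and the
conditional permutation law are genuinely different objects at that sample
size. Discrepancies of that size never flipped a clear α = 0.05 conclusion
in our checks, but users comparing models with borderline p-values may
prefer the permutation route. No multiple-testing correction is applied
across the 36 pairwise comparisons.

Identical prediction vectors are reported as z = 0, p = 1 rather than an
error (the degenerate-correlation guard applies to the accuracy
correlations themselves).

## Stability

For each single-type model, each feature's selection frequency is its
fold-count ratio; "common predictive features" are those with frequency
strictly above ½ (a feature at exactly 0.5 is not retained). Regional
features map voxel → region through the parcellation; connectivity
features become order-normalised region pairs; per-region voxel counts and
per-pair edge counts give the summary tables. For fused models stability
is reported per constituent, since selection only ever happens within
single-type models.

## The synthetic cohort

**Thresholds.** The observation model mimics an ascending method-of-limits
staircase: a latent threshold (affine in the planted features plus
Gaussian noise) is measured twice; each measurement adds noise and snaps
*up* to the first grid value 1.0, 1.25, 1.5, … J at or above it (ascending
stimuli can only overshoot); the reported threshold is the mean of the
two, hence lies on the 0.125 J grid. Snapping adds ≈ +0.125 J in mean and
a small variance; the default intercept 2.445 J compensates, so the
default population lands at ≈ 2.57 ± 0.53 J (verified at n = 1000 in the
tests). Test–retest noise of the two measurements is a free parameter
(default 0.05 J) because no empirical value is available.

**Feature tables.** Each block b ∈ {reho, fc, fa, sc} carries a
unit-variance latent signal s_b = sqrt(ρ)·g0 + sqrt(1−ρ)·g_b; the
redundancy knob ρ interpolates between fully shared signal (ρ = 1, the
modalities overlap) and independent block signals (ρ = 0, they
complement). Planted columns are s_b plus feature noise (sd 0.5); null
columns are iid standard normal. The latent threshold combines the block
signals with equal weights, variance-rescaled so the calibration above
holds at every ρ. The default weights make each block explain exactly one
quarter of the latent threshold variance — the boundary at which four
blocks plus the 2.57 ± 0.53 J calibration are simultaneously satisfiable —
so the residual variance of reported thresholds comes from the staircase
observation model alone. Default dimensions are the desk-scale study:
210 subjects, 500 columns per regional block, 90-ROI (4005-column)
connectivity blocks, 10 planted columns per block, ρ = 0.

**Volumes.** Parcellations grow connected ROIs from random seeds by
multi-source breadth-first expansion. BOLD voxels mix an ROI-level latent
series (drawn with a configurable R×R covariance) with iid noise through a
local-coherence weight — exactly the structure ReHo and FC measure. Motion
traces are smoothed Gaussian walks rescaled so a chosen fraction of frames
crosses the scrubbing threshold. Tensor fields assign each voxel a prolate
tensor solving the FA formula in closed form at a fixed trace
(d = λ1 − λ2 = FA·trace/sqrt(3 − 2·FA²)), oriented randomly except inside
straight inter-ROI "bundle" corridors, which get the corridor direction
and elevated FA; FA round-trips through the extraction to 1e−10.

**What passing does and does not show.** The generator emulates the
*statistical* structure the pipeline assumes — linear signal, staircase
quantisation, block redundancy, corridor-like bundles — not MR physics:
no hemodynamic response, no k-space noise, no crossing fibres, no
registration error. Passing tests demonstrate that the procedure is
implemented correctly, leaks no labels, and recovers planted effects of
realistic size; they cannot certify performance numbers on real cohorts.

## Numerical choices and edge cases

- Fisher-z clip at |r| = 1 − 1e−7; FA targets must be < 1 (FA = 1 needs a
  degenerate tensor and is produced only by `fa_from_eigenvalues` itself).
- Rank-deficient nuisance designs error with the offending columns named;
  the intercept is always added.
- The band-pass retains bins with low ≤ f ≤ high and always removes DC.
- Voxel indices are 1-based linear indices throughout (R convention),
  documented wherever they surface in TSV metadata.
- Per-fold regressor seeds derive deterministically from the model seed,
  so an entire suite is bit-identical under a fixed seed.
- LOOCV with fold-wise selection is *pessimistically* biased under the
  null: fold-adaptive selection of currently-overfit null columns, and the
  training-mean fallback, both anticorrelate with the held-out label. On
  noise-only tables the mean out-of-fold correlation is visibly negative
  (≈ −0.2 in our n = 100 checks); the suite asserts the absence of
  *optimistic* bias. The same mechanism noticeably drags down single-type
  accuracy when the candidate pool is large (4005 connectivity columns),
  which is why connectivity models trail regional ones on equal planted
  signal — mirroring the ordering typically seen in applications.

## Study sizes used by the scripts and tests

The analysis scripts run the full desk-scale study (210 subjects,
500/4005-column blocks); the imaging demo and end-to-end tests use an
8×8×8 grid, 6 ROIs, 40 subjects, 60 frames, and 1–50 streamlines per seed
voxel. The statistical-calibration checks use 2000 null replicates and
3000-permutation oracles. These sizes were chosen so the whole suite
replays comfortably on a single CPU while keeping every Monte-Carlo
tolerance in the regime its standard error justifies.

## Known limitations

- Single-tensor tractography cannot express crossing or kissing fibres;
  corridor phantoms are the intended regime.
- The ReHo neighbourhood is truncated at mask edges rather than padded;
  voxels with K < 4 are zeroed, which slightly shrinks edge statistics.
- The dependent-correlation z is an asymptotic approximation; see the
  evaluation section for its conditional behaviour.
- Fusion is the plain mean by design; no stacking or weighting schemes are
  provided.
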