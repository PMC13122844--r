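---
title: "Functional phenotyping of sensorimotor cortex in ALS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional phenotyping of sensorimotor cortex in ALS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcphen)
```

# Scope

Amyotrophic lateral sclerosis (ALS) presents focally — symptoms start in
one body part and spread — and its functional signature in the
somatotopically organized primary motor cortex is of direct clinical
interest. `funcphen` implements a complete task-fMRI analysis chain for
individualized functional phenotyping of the sensorimotor cortex in ALS:

1. block-design preprocessing (band-pass, standardization, run handling),
2. first-level GLM functional localizers with fixed-size top-k masks,
3. eigenvector centrality mapping (ECM) and seed-based connectivity with
   stage-wise patient–control contrasts,
4. robust Shared Response Modelling (rSRM) with *dual* group shared
   spaces feeding a leave-one-subject-out (LOSO) SVM group classifier,
5. NIPALS partial least squares regression (PLSR) relating voxel-wise
   functional features to clinical scores (ALSFRS-R, PUMNS), with
   leave-one-out validation, weight back-projection and region-wise
   statistics.

Because no public cohort is available at desk scale, a first-class
synthetic cohort generator (`generate_cohort()`) emulates the statistical
structure every stage assumes and provides ground truth for recovery
testing. All stages run end-to-end via `run_pipeline()`.

# The generative world

`cohort_config()` fixes a two-group cohort (default 14 patients, 12
controls, mirroring the emulated study) on a voxel grid carrying five
disjoint somatotopic clusters: left/right hand (LH, RH), left/right foot
(LF, RF) and tongue/face (TONGUE). Each subject performs 12-s movement
blocks separated by 15-s rest (4 repetitions of each of the 5 conditions
by default; rest also precedes the first and follows the last block, so
a run lasts 555 s at TR = 2 s), in a subject-specific randomized order.

Per subject, the voxel-by-time data are

\[
X_i \;=\; W_i\,R_g \;+\; S_i \;+\; A_i \;+\; M_i \;+\; E_i ,
\]

* **Shared response.** $R_g$ ($k \times T$, one per group) holds smooth
  latent time courses; $W_i$ ($V \times k$) is a subject-specific basis
  with orthonormal columns. $R_g$ is scaled by $\sqrt{V/k}$ so the
  shared component has roughly unit per-voxel variance — in task fMRI
  the synchronized task-driven response dominates, and the generator's
  `snr` is defined against it. Crucially, $R_g$ lives in *canonical*
  (condition-locked) time: it enters each subject's series through the
  inverse of that subject's synchronization permutation, so subjects
  with different block orders align onto the same $R_g$ only after
  `synchronize_blocks()` — exactly the premise of shared response
  modelling on block designs. A `shared_condition_locked = FALSE`
  switch instead unfolds $R_g$ in raw acquisition time (generic,
  condition-unrelated shared activity); the localizer recovery tests
  use that world, since there the activation term must be the only
  condition-locked signal.
* **Sparse individual term.** $S_i$ has i.i.d. Bernoulli(0.05) support
  with Gaussian amplitudes — the model class the robust SRM assumes.
* **Activation.** $A_i$ places HRF-convolved boxcar responses
  (amplitude 1) of each condition in that condition's ROI cluster.
* **Connectivity structure.** A smooth per-subject latent $g_i(t)$ is
  mixed into every ROI voxel. Patients' mixing amplitude is modulated
  per King's stage with the inverted-U signs the study reports
  (defaults $-0.10, +0.12, -0.20$; converted to amplitude units by an
  empirically matched factor, `conn_offset_scale`). On top, a
  continuous severity latent $s_i \approx (\text{stage}-1)$
  *redistributes* the coupling within the foot and tongue fields using
  zero-mean voxel loadings: some voxels gain hubness with severity,
  others lose it, and no net centrality mass leaves the hand fields.
  The zero-mean form matters: eigenvector centrality is unit-norm, so
  a net mass transfer into the (larger) foot+tongue territory would be
  absorbed by the (smaller) hand territory at ~1.5x the per-voxel
  amplitude, structurally inverting the foot/tongue-dominant weight
  signature the study reports.
* **Clinical scores.** ALSFRS-R decreases linearly with $s_i$
  (plus Gaussian noise, `clinical_noise_sd`); PUMNS increases with an
  upper-limb-onset indicator plus a weaker severity term. Stage and
  onset frequencies mirror the study (6/4/4 stages, 8 UL / 3 LL / 3 B).
* **Noise.** $E_i$ is i.i.d. Gaussian with
  $\mathrm{sd} = \mathrm{sd}(W_iR_g + A_i)/\mathrm{snr}$.

There is no baseline term by default (`baseline = 0`); a nonzero
baseline is available for demonstrating per cent signal change on
raw-unit data. The generator does **not** emulate physiological noise,
motion, scanner drift, spatial autocorrelation or multi-run sessions —
a green test establishes correctness of the estimators on this stated
world, not robustness to artifacts the study handled upstream (motion
correction, smoothing, registration are out of scope).

All randomness descends from one integer seed through a labelled
hash-splitting scheme (`split_seed()`), so stages are independently
reproducible.

# Preprocessing

`bandpass()` applies a 4th-order Butterworth band-pass (0.01–0.1 Hz by
default), realized as cascaded second-order sections and applied
forward–backward with odd-reflection padding — numerically stable at the
very low normalized frequencies of fMRI and zero-phase by construction.
The implementation matches `scipy.signal.sosfiltfilt` to ~1e-14 at equal
padding. DC is rejected exactly (zeros at $z = 1$).

`synchronize_blocks()` re-orders frames so condition blocks appear in
the canonical order LH, RH, LF, RF, TONGUE, each block carrying its
movement window plus the following rest window; lead-in rest frames stay
in place as a baseline prefix. With TR = 2 s the 27-s block+rest cycle
covers 13.5 frames, so window frame counts alternate 13/14 with slot
parity; every window is truncated to the common minimum and the leftover
late-rest frames are collected in a rest tail. This makes the canonical
condition-time alignment *identical* across subjects (a requirement for
shared response modelling) at the cost of the last rest frame of every
other block being re-ordered to the end; total length is preserved and
the mapping remains a permutation.

`split_runs()` takes the first $\lfloor T/2 \rfloor$ frames as Run 1 and
the rest as Run 2. `percent_signal_change()` computes, per block,
$100\,(\bar{x}_\text{task} - \bar{x}_\text{flanking rest}) /
\bar{x}^\text{raw}_\text{flanking rest}$, averaged over region voxels
and blocks. The study standardizes before PSC, which destroys the
baseline denominator; we therefore take the numerator from the filtered
series and the denominator from the raw series (both are explicit
arguments, so the all-filtered variant is one call away).

# Localizers

`fit_glm()` is an ordinary least squares GLM with one HRF-convolved
boxcar per condition plus an intercept; $t$-statistics test each
condition against baseline with residual degrees of freedom. No
autocorrelation correction is applied (a documented deviation from SPM's
prewhitening; the type-I calibration test shows the nominal 5% level
holds on white-noise voxels, which is what the generator produces).
`top_k_mask()` keeps the k most active voxels (fixed-size masks avoid
penalizing patients with weaker movements), with lexicographic
tie-breaking for determinism. `group_mask()` intersects per-subject
masks and keeps the largest connected component (26-neighbourhood by
default, 6 available); `combined_mask()` unions condition masks.

# Connectivity

`ecm()` scores voxel hubness as the principal eigenvector of the
similarity matrix $(r+1)/2$ (shifted Pearson correlations; strictly
positive, so Perron–Frobenius guarantees a unique non-negative
eigenvector), computed by power iteration to 1e-10. `max(r, 0)` is
available as an alternative similarity. The map is returned with unit
Euclidean norm — whether the original ECM tooling rescales for display
is unknown, so unit norm is the contract here.

`seed_connectivity()` correlates each in-mask voxel's z-scored time
course with the z-scored mean course of a Euclidean ball of radius 5
voxels around the seed centre (the peak-$t$ voxel of each condition's
group mask in the pipeline). `stage_contrast()` averages
patient-minus-matched-control map means per King's stage; on default
cohorts the stage profile reproduces the reported inverted-U signs
$(-, +, -)$.

# Dual-space rSRM classification

`fit_rsrm()` minimizes
\[
\sum_i \lVert X_i - W_i R - S_i \rVert_F^2 + \gamma \sum_i \lVert S_i \rVert_1
\]
by exact block-coordinate descent: orthogonal Procrustes for each $W_i$
(SVD polar factor of $(X_i - S_i) R^\top$), averaging for $R$, and
entrywise soft-thresholding at $\gamma/2$ for $S_i$. Every update is a
block minimizer, so the recorded objective trace is non-increasing — an
invariant asserted in tests. $\gamma$ defaults to
$0.1\,\mathrm{median}|X|$ (the study states no penalty); $k$ defaults
to 10 and the shared dimension of any analysis must satisfy
$k \le \min(V, T)$. Initialization is seeded (random orthonormal bases);
`w_init` allows warm starts and reference comparisons — the objective is
non-convex, so the gamma = 0 equivalence test against an independent
alternating-Procrustes implementation shares its starting point.

For classification, two rSRMs are fit per LOSO fold on the training
subjects' Run-1 data: one on the remaining patients, one on the
remaining controls. Each subject's basis is learned from its Run 1
against each frozen shared response (`transfer_basis()`: Procrustes,
one soft-threshold pass, Procrustes again), Run 2 is projected through
both bases (`project_shared()`, discarding the individual term), and the
two $k \times T_2$ projections are flattened frame-major and
concatenated — patient space first (`dual_space_features()`).

The classifier is a linear soft-margin SVM (C = 1) solved by dual
coordinate descent, with two protocol elements that matter for
calibration:

* **Feature centering.** Dual-space features share a large common
  component (the shared response itself); without removing the training
  column means, every pairwise inner product is dominated by it and any
  residual class-cost imbalance pushes all predictions to one side.
* **Balanced folds.** A LOSO fold is necessarily imbalanced against the
  held-out label (its class has one member fewer in training). A
  maximum-margin classifier then favours the majority class, which
  *anti*-predicts the held-out subject: under label permutations the
  mean accuracy falls well below the binary chance level of 0.5 (we
  measured 0.26–0.44 for the naive protocol). Randomly subsampling the
  majority class to balance each training fold removes the asymmetry;
  the permuted-label mean accuracy is then statistically
  indistinguishable from 0.5 (0.5025 ± 0.0086 over 400 permutations)
  while true-label separation is unaffected.

`loso_permutation_test()` calibrates chance empirically by permuting the
class labels at the classification stage: the per-fold models and
features are label-independent under this null and are computed once,
and the per-fold SVMs are retrained under each permutation. This is the
standard permutation test of a cross-validated classifier; pushing the
permutation through the rSRM fits as well would multiply the cost by the
permutation count and, because training subjects are "insiders" of their
own group model while the held-out subject is not, would anti-bias any
implementation of the per-fold scheme below 0.5.

`affected_contrast()` pools patient fold accuracies (0/1 per
subject x ROI) into first-affected versus non-first-affected groups —
onset type maps UL to {LH, RH}, LL to {LF, RF}, B to {TONGUE}; per-limb
laterality is not recoverable from the clinical table, so limb onsets
are treated bilaterally like bulbar onset — and compares them with a
pooled-variance two-sample t-test. Zero-variance groups return the
degenerate convention ($t = \pm\infty$, $p = 0$) flagged explicitly.

# PLSR

`fit_plsr()` implements NIPALS: components maximize the covariance
between predictor and response scores; the first weight vector equals
the dominant left singular vector of $X_c^\top Y_c$; $X$ is deflated per
component and the coefficient matrix is $W (P^\top W)^{-1} C^\top$.
Predictors are mean-centered, not variance-scaled, by default (the
study is silent; a `standardize` flag exists — note that scaling changes
the weights but not the LOO-error ordering against a permuted-response
null). `loo_cv()` reports per-fold MSE (squared error for the single
held-out subject, averaged over response dimensions) and the held-out
subject's first two latent coordinates. ALSFRS-R and PUMNS are modelled
in separate single-response runs, L = 2 throughout by default (the
study reports LV1/LV2 scatters and names a two-component model).

`run_plsr_analysis()` builds the predictor matrix over the combined
mask: ECM values per voxel, GLM activation t values per voxel (per
voxel the largest condition t — the study is ambiguous between t-maps
and extracted time series for the activation predictor, so both are
predictor choices; default t-maps for ALSFRS-R, time series for PUMNS),
or the flattened masked time series. For time-series predictors the
back-projected voxel weight is the mean |w| over that voxel's frames.
`region_weight_stats()` computes one observation per subject-fold per
region (mean |weight|), a one-way repeated-measures ANOVA
($F = MS_\text{region}/MS_{\text{region}\times\text{subject}}$) and
Holm-adjusted pairwise paired t-tests.

# What the recovery tests do and do not establish

* **rSRM recovery** runs on *model-class* cohorts (activation and
  latent mixing disabled; sparse individual terms and noise at
  snr = 10 on). With the activation term enabled, post-synchronization
  activation is genuinely shared across subjects, and a correct rSRM
  absorbs it into the shared space — the generative $R_g$ alone is then
  not the estimand, so comparing against it would penalize correct
  behaviour. Recovery correlation per subject exceeds 0.95.
* **Localizer recovery** uses the `shared_condition_locked = FALSE`
  world (shared activity unrelated to the design) and the full
  4-repetition paradigm; mean Jaccard between top-k masks and true
  clusters at snr = 5 exceeds 0.9 over 20 seeds. With a condition-locked
  shared response, shared activity is itself "activation" everywhere
  and fixed-size localizers legitimately blur.
* **PLSR recovery** correlates first-component weights with the
  generative severity loadings (|r| ≥ 0.7 at clinical noise 0.1); the
  LV1 score separates stage-3 from stage-1/2 patients (balanced
  accuracy ≥ 0.75 of the optimally oriented sign rule) in well over 90%
  of seeds.

# Numerical choices and degenerate inputs

* Power iteration: relative tolerance 1e-10, 1000 iterations, error on
  non-convergence; constant voxel time courses are an error for
  connectivity maps, a warning (column zeroed) for z-scoring, and t = 0
  with a warning for all-zero GLM voxels.
* rSRM stops at relative objective change below 1e-6 (100 sweeps by
  default; permutation studies cap sweeps at 50 to bound runtime —
  under permuted labels fit precision is immaterial).
* NIPALS inner loop: tolerance 1e-12, 500 iterations (single-response
  models converge in one pass).
* Ties: top-k masks break t ties lexicographically by voxel index;
  equally sized connected components resolve to the one containing the
  lexicographically smallest voxel.
* Holm-adjusted p-values are monotone step-down and clipped at 1;
  zero-variance paired differences yield t = 0, p = 1.
* The clinical-table fixture reproduces the published patient table
  verbatim; its printed summary statistics (ALSFRS-R mean/range, PUMNS
  mean) differ slightly from the table itself in the source — the
  fixture follows the table and the discrepancy is documented, not
  resolved.

# Known limitations

* The generator's effect sizes for group differences in activation
  amplitude are free parameters (the study reports none); defaults are
  fixed once and documented above.
* The voxel grids used in tests are small (hundreds of voxels); nothing
  in the implementation is specific to that scale, but runtimes on
  full-resolution 7T grids will be dominated by the per-fold rSRM fits.
* `run_pipeline()` estimates seed centres and ROI masks from the data
  (as the study does); on very small synthetic cohorts the intersection
  masks can become smaller than the shared dimension, in which case the
  affected ROIs are skipped with a warning.
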