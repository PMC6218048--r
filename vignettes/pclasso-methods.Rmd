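---
title: "PC-LASSO: voxel covariance patterns and penalized prediction in parametric brain PET"
author: "PCLassoPET authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PC-LASSO methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PCLassoPET)
```

## The problem

Conventional quantification of brain PET reduces a region of interest
(ROI) to its mean tracer uptake, discarding the *spatial distribution* of
binding inside the ROI. In progressive disorders such as Parkinson's
disease (PD), degeneration develops along characteristic spatial
gradients — for the presynaptic dopaminergic system, posterior putamen
before anterior putamen — so the within-ROI pattern carries clinical
information the mean cannot.

PCLassoPET implements a two-stage, data-driven analysis of parametric
binding-ratio (BR) images that are already resampled into a common labeled
template space:

1. **Pattern discovery.** Voxel-wise principal component analysis (PCA) of
   the subject-by-voxel BR matrix identifies orthonormal voxel covariance
   patterns (PC loadings) and per-subject expression scores, blindly with
   respect to any clinical variable.
2. **Penalized prediction.** The leading PC scores (plus optional clinical
   covariates) enter an L1-penalized (LASSO) linear model of a clinical
   metric, with the penalty chosen by repeated random-holdout
   cross-validation. Because both stages are linear, the fitted model is
   back-transformed into a single voxel-weight map — the *PC-LASSO
   estimator* — whose inner product with a subject's image predicts the
   metric directly.

## Data model and conventions

* **BR images**: voxel activity divided by the mean activity over a
  nonspecific reference region (`computeBR`). The mean (not the median) is
  used. BR is dimensionless and nonnegative; the analysis operates on
  covariance patterns, not absolute values, so any parametric image type
  with consistent scaling can be substituted.
* **Template space**: a `LabeledTemplate` with labels 0 (background),
  1 (putamen), 2 (caudate + ventral striatum), and anatomical axes
  LM/AP/IS. Spatial normalization itself is out of scope: images must
  arrive on the template grid, and a shape check rejects anything else.
* **Voxel order**: all flattened ROI vectors use lexicographic order over
  the 0-based (i, j, k) template indices, making every matrix column order
  reproducible across runs.
* **Sides**: hemisphere images are relabeled *better*/*worse* as the sides
  contralateral to the less/more affected body side (`sortSides`), with
  the worse body side taken from the lateralized MDS-UPDRS III totals
  (`assignSides`). Lateral totals can tie; the tie-break is deterministic
  (worse = right) and always warned about, because it is a convention, not
  a clinical judgment.

## Clinical metrics

* **LMS** (lateral motor score): the sum of the seven lateralized limb
  items (leg rigidity, toe tapping, leg agility, arm rigidity, finger
  tapping, hand movements, pronation/supination), in [0, 28] per body
  side. Tremor items are excluded deliberately — tremor correlates poorly
  with dopaminergic denervation.
* **aDD** (adjusted disease duration): presynaptic binding declines
  approximately exponentially in disease duration DD, so linear models are
  fitted against the linearized quantity
  `aDD(DD) = M * (1 - exp(r DD)) / (1 - exp(r M))`, with `r = -0.17`/year
  (obtainable from the data at hand through `fitADDRate`, which fits
  `BR = a exp(r DD)` by Levenberg–Marquardt) and `M = 16` years the upper
  end of the renormalization range. The renormalization is the unique
  *increasing affine* map of `exp(r DD)` fixing `aDD(0) = 0` and
  `aDD(M) = M`; an affine map is the minimal choice consistent with
  "increasing with progression, spanning the DD range". DD beyond `M` is
  extrapolated by the same formula with a warning.

## PCA stage

`fitPCA` removes the per-voxel mean and takes the SVD of the centered
N-by-V matrix. Deliberate numerical choices:

* **Covariance, not correlation, PCA.** Voxels are commensurate BR values;
  scaling each voxel to unit variance would destroy the interpretation of
  the first component as a weighted mean of the ROI.
* **K = min(N − 1, V)** components; variance accounted for (VAF) is the
  percentage of total centered variance, so VAF sums to 100 at full rank
  and the reconstruction `mean + scores %*% loadings` is exact to
  numerical precision.
* **Sign canonicalization.** PCA leaves loading signs free. Each loading
  is flipped so its weight sum is nonnegative (with its score column
  flipped too); an exactly zero-sum loading has its largest-magnitude
  weight made positive. This is a package convention for reproducibility —
  flipped loadings are equivalent.
* Degenerate input (zero variance) is an error, not a silent all-zero
  decomposition.

Stage-stratified PCA (`runSubgroupPCA`) re-runs the decomposition on
preset subgroups — mixed HC plus PD with DD ≤ 2 years, early PD
(DD ≤ 3), moderate PD (DD ≥ 4) — optionally excluding agonist-ON subjects
(chronic dopamine-agonist treatment alters postsynaptic tracer binding).
`compareLoadings` quantifies pattern consistency as |cosine| between
loadings, which is invariant to the sign ambiguity.

## LASSO stage

`lassoSolve` minimizes

    0.5 * sum_n (y_n - b0 - sum_j x_nj b_j)^2 + lambda * sum_j |b_j|

by cyclic coordinate descent with soft-thresholding on the centered
problem, using the Gram matrix so each coordinate update is O(J). The
intercept is unpenalized. Convergence is declared when the largest
coefficient change in a sweep falls below 1e-8; non-convergence within the
sweep budget is an error with diagnostics, never a silent result. At
`lambda = 0` the solution equals ordinary least squares; at
`lambda >= lambdaMax(X, y) = max_j |x_j' (y - mean(y))|` the model is
intercept-only.

Model selection follows the repeated-holdout protocol:

* the penalty grid is **linear** from 0 to lambda_max in 100 steps (101
  values) — not the conventional log grid — because the search is defined
  over the full range down to the OLS limit;
* lambda_max is computed once on the full standardized data and the same
  grid is reused across splits (recomputing it per split would make the
  grids incomparable when averaging);
* 500 random train/test splits by default (the desk-scale profile in
  `runConfig` uses 100) at holdout fraction 0.3, test size
  `round(0.3 N)`, sampled without replacement, each split seeded from a
  single master seed so that the constant, mean-BR and PC-LASSO models can
  share the identical split sequence;
* **standardization is recomputed inside every training split** and
  applied to its test half: predictors (PC scores *and* covariates) are
  z-scored and penalized equally, the plain reading of the objective;
* `lambda_min` is the grid value minimizing the mean test MSE, ties broken
  toward the **larger** penalty (prefer sparsity when accuracy is
  indistinguishable);
* MSE_all is the full-data MSE of the full-data fit at lambda_min;
  per-split coefficients at lambda_min are reported as mean and SD on the
  raw input scale (standardized coefficients divided by the training-split
  SD), which makes them comparable across splits;
* p-values of retained coefficients come from a **post-selection OLS
  refit** on the active set (two-sided t-tests). This is a package
  decision — recorded in the result metadata — since classical inference
  after L1 selection is not uniquely defined; these p-values are
  descriptive, not selection-adjusted.

Reference models (`fitReferenceModels`) are evaluated with the same
protocol on the same splits: a constant model (training-mean prediction;
its MSE_all is the biased sample variance of the outcome, the "no
information" baseline) and a one-predictor least-squares model on the mean
ROI BR.

A known behavior worth stating: the MSE-optimal penalty tends to
*over-select*. Inputs carrying no signal often keep small nonzero
coefficients at lambda_min, because zeroing them changes test MSE only
marginally. The package reports the retained set as fitted; sparsity
beyond what prediction accuracy demands is not enforced.

## The estimator map

Writing the fitted model in score space as `y = b0 + sum_j s_j b_j` and
substituting `s_j = (f - mean) . omega_j` gives
`y = b0' + (f - mean) . v` with `v = sum_j b_j omega_j` (raw-score-scale
coefficients). `computeEstimator` assembles `v`; covariate coefficients
have no voxel support and are carried beside the map, never folded into
it. The per-voxel mean term is folded into the reported intercept, so the
score-space and voxel-space predictions agree to machine precision for
every subject — the package's central algebraic identity, asserted in the
test suite. The printed equations leave the centering convention open; the
equivalence-preserving convention is chosen and documented here.

`mipRender` visualizes a map as maximum-intensity projections along an
anatomical axis: positive weights and magnitudes of negative weights are
projected separately and both normalized by the global maximum absolute
weight (the normalization factor is reported). Front/back views are the
two AP-axis projections.

## The phantom generator

Because no real cohort is distributed, the phantom module generates
complete synthetic studies with known ground truth:

* **Template**: two disjoint axis-aligned ellipsoids on a 32 x 48 x 32
  grid — putamen elongated along AP, caudate+VS along IS — the simplest
  geometry supporting the anatomical gradient directions of interest.
* **Patterns**: a constant all-positive pattern, mean-centered linear
  ramps (AP, IS, or a ventromedial-dorsolateral diagonal), and
  deterministic pseudo-random patterns, orthonormalized sequentially with
  the global pattern first so it stays all-positive (mirroring the
  empirical finding that the first PC is a weighted mean).
* **Cohort coupling**: DD is uniform on [0, 16] years; scores are linear
  in aDD with Gaussian noise; LMS is linear in selected pattern scores;
  the worse side reuses the better-side basis with an additive score
  offset, so worse-side patterns are "more progressed" better-side
  patterns.
* **Images**: `mean_level + sum_k s_nk omega_k` plus iid Gaussian voxel
  noise, clipped at zero (BR is a nonnegative ratio; at the default noise
  level clipping is essentially never active, so the planted
  decomposition is preserved).

Defaults are fixed once as the modeled study conditions: 40 subjects (the
cross-validated sample size), mean BR level 2.0 (a typical striatal
presynaptic value), voxel noise SD 0.1 = 0.05 x mean level, pattern-1
scores declining with aDD (slope −1.5, SD 1.0), patterns 2 and 3 varying
independently (SD 3.0 and 2.0), LMS driven by patterns 1 and 3 with
outcome noise SD 0.4 (about 0.1 x the outcome SD), and a worse-side
offset of −2 on pattern 1. No quantitative SNR for real BR images is
available to copy, so these values are chosen for testability with
realistic orders of magnitude, and they are not revisited per analysis.

What the phantom does *not* emulate: real anatomy, partial-volume and
resolution effects, tracer kinetics, registration error, and non-Gaussian
or spatially correlated noise. Passing recovery tests therefore
demonstrates correctness of the computational chain under the stated
generative model, not clinical performance on real images.

## Problem sizes and reproducibility

The test suite runs phantoms on a 16 x 24 x 16 template (about 350
putamen voxels) for fast unit checks and on the full default template for
the 20-seed recovery, selection and model-comparison studies, using the
100-split CV profile; these sizes were chosen so the whole suite exercises
every stage in a few minutes while keeping the statistical checks
well-powered. All randomness flows from explicit integer seeds: the
phantom spec seed drives cohort sampling, a separate seed drives voxel
noise, and a CV master seed spawns per-split seeds, so identical
configurations yield byte-identical tabular outputs.

## Known limitations

* Linear models throughout; metrics that respond non-linearly must be
  linearized first (as aDD does for DD), and the right transformation may
  not be known a priori for other metrics or tracers.
* PC loading signs are canonical only per decomposition; matching
  loadings across datasets uses |cosine|, which ignores small weight
  differences rather than modeling them.
* Post-selection p-values are unadjusted for the selection event.
* The estimator map inherits the ROI restriction and the template
  resolution; it says nothing about voxels outside the analyzed ROI.
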