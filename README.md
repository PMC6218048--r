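# PCLassoPET

Data-driven, voxel-based analysis of parametric brain PET images:
voxel-wise PCA pattern discovery, LASSO-regularized prediction of clinical
metrics from pattern scores, and back-transformation of fitted models into
interpretable voxel-weight estimator maps.

## The problem and who it is for

Standard ROI analysis of PET reduces a structure to its mean tracer
binding, discarding the spatial pattern of binding inside the ROI. In
progressive disorders such as Parkinson's disease the within-ROI pattern
(e.g. the posterior-to-anterior gradient of presynaptic denervation in the
putamen) carries clinical information of its own. PCLassoPET is for
imaging researchers who have parametric binding-ratio (BR) images already
warped into a common labeled template space, plus a clinical table, and
who want interpretable, cross-validated image-based models of clinical
metrics rather than opaque radiomic features.

## The method

With `f_n` the vector of ROI voxel BR values of subject *n*:

1. **PCA** (per ROI, per hemisphere side): `f_n = mean + sum_k s_nk w_k`,
   where the orthonormal loadings `w_k` are voxel covariance patterns and
   the scores `s_nk` quantify each subject's expression of pattern *k*.
   Components are ranked by variance accounted for (VAF).
2. **LASSO** over the top-J scores (default J = 5) and optional clinical
   covariates:

       min over b:  0.5 * sum_n (y_n - b0 - sum_j x_nj b_j)^2 + lambda * sum_j |b_j|

   solved by cyclic coordinate descent with soft-thresholding. The penalty
   is selected on a linear grid from 0 to lambda_max (the intercept-only
   bound) by repeated random-holdout cross-validation (default 500 splits
   at holdout 0.3), minimizing mean test MSE; constant and mean-BR
   reference models are evaluated on identical splits.
3. **Estimator map**: since both stages are linear, the fitted model
   collapses to `y = b0' + (f - mean) . v` with `v = sum_j b_j w_j` — a
   single voxel-weight map whose inner product with an image predicts the
   metric. Maximum-intensity projections of the positive and negative
   weights visualize it anatomically.

Clinical support includes the lateral motor score (sum of seven
lateralized MDS-UPDRS III limb items, tremor excluded), better/worse side
assignment (hemisphere contralateral to the more affected body side), and
adjusted disease duration `aDD = M (1 - exp(r DD)) / (1 - exp(r M))` with
`r = -0.17`/year, `M = 16` years, which linearizes the exponential decline
of presynaptic binding.

A synthetic striatal phantom generator (ellipsoidal putamen/caudate
template, orthonormal planted patterns, scores coupled to disease
duration and motor scores, hemispheric asymmetry, voxel noise) provides a
complete ground-truth test surface; see the methods vignette
(`vignettes/pclasso-methods.Rmd`) for the generative model and all design
decisions.

## Worked example

A phantom cohort of 40 subjects with three planted patterns, where the
lateral motor score is generated from patterns 1 and 3:

```r
library(PCLassoPET)

template <- makeTemplate()
basis <- makePlantedBasis(template, kinds = c("global_positive",
                                              "ap_gradient", "is_gradient"))
spec <- cohortSpec(seed = 42L)
cohort <- sampleCohort(spec, basis)
images <- renderImages(template, basis, cohort$scores$better,
                       noise_sigma = spec$noise_sigma, seed = 43L)

vm <- extractVoxelMatrix(images, template, roi_label = 1L)  # putamen
pcd <- fitPCA(vm)
pcd
#> PCDecomposition: 39 PCs over 1723 voxels, 40 subjects
#>   VAF (%): 63.7 9.0 5.2 0.8 0.8

round(diag(compareLoadings(pcd, basis, top_k = 3)), 3)
#> [1] 0.980 0.879 0.861
```

The first three PCs recover the planted patterns (|cosine| against ground
truth); VAF drops to the 0.8% noise floor afterwards. Now the prediction
stage, with the reference model on shared splits:

```r
y <- cohort$clinical$LMS_better
splits <- makeSplits(spec$n_subjects, n_splits = 100L, seed = 7L)
cv <- repeatedHoldoutCV(patternScores(pcd)[, 1:5], y, splits = splits,
                        outcome_name = "LMS_better")
cv
#> CVResult [pclasso] outcome=LMS_better, 100 splits
#>   lambda_min=1.082  MSE_test=0.184  MSE_all=0.1312

refs <- fitReferenceModels(rowMeans(voxelData(vm)), y, splits,
                           outcome_name = "LMS_better")
refs$mean_br
#> CVResult [mean_br] outcome=LMS_better, 100 splits
#>   MSE_test=6.359  MSE_all=5.486

cv@retained_terms
#> [1] "PC1" "PC2" "PC3"
```

The PC-LASSO model's cross-validated test MSE (0.18, in LMS units
squared) is far below the mean-BR baseline (6.36): the gradient patterns
carry motor-score information the ROI mean cannot express. The signal
patterns 1 and 3 are retained; note that MSE-optimal penalties typically
also keep small coefficients on non-signal inputs (here PC2). Finally the
voxel-space estimator:

```r
est <- computeEstimator(pcd, cv@full_model)
est
#> EstimatorMap over 1723 voxels; |v| range [-0.0773, 0.0563]

max(abs(predict(cv@full_model, patternScores(pcd)[, 1:5]) -
          predictFromVoxels(est, vm)))
#> [1] 1.24345e-14

mip <- mipRender(est, "AP", grid_shape = dim(templateLabels(template)))
mip$norm_factor
#> [1] 0.0773258
```

Score-space and voxel-space predictions are identical to machine
precision, and `mipRender` yields the normalized positive/negative weight
projections for display.

The same flow is available end-to-end through `runPhantomDemo`,
`runPatternAnalysis` and `runPrediction` (JSON-configured; see
`runConfig`), or from a shell via `exec/pclasso` with subcommands
`patterns`, `predict`, `phantom` and `br`.

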