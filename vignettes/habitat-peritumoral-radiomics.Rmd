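---
title: "Habitat and peritumoral radiomics: models, design choices, and what the synthetic cohorts do and do not show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat and peritumoral radiomics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(habitatbm)
```

## The problem and the pipeline

`habitatbm` implements a habitat–peritumoral radiomics pipeline for
predicting a binary treatment response from 3D lesion MRI plus clinical
covariates. The pipeline has eight stages:

1. **Synthetic cohorts** (`generate_cohort`): lesions with latent phenotype
   subregions, a peritumoral halo, multiplicative bias fields, anisotropic
   native voxel spacing, and a clinical table whose response follows a
   documented logistic model.
2. **Preprocessing** (`correct_bias`, `resample_isotropic`,
   `select_dominant_lesion`, `icc_agreement`): log-domain bias-field
   correction, 1 mm isovoxel resampling, dominant-lesion selection, and
   inter-observer agreement via ICC(2,1).
3. **Habitat discovery** (`local_features`, `select_k`, `fit_habitats`,
   `assign_habitats`): a 5×5×5 moving window produces 19 per-voxel
   statistics; voxels pooled across the training cohort are clustered with
   K-means; the cluster count is chosen where the Calinski–Harabasz,
   Davies–Bouldin and Silhouette indices agree; stability is scored as the
   mean pairwise voxel agreement between ten seeded runs after Hungarian
   label matching.
4. **Peritumoral rings** (`peritumoral_ring`, `build_region_set`): shells at
   1/2/3 mm physical distance from the tumor boundary, from an exact
   Euclidean distance transform.
5. **Feature extraction** (`filter_bank`, `extract_region_features`,
   `fuse_habitat_features`): an IBSI-style bank of 1834 features per region
   (14 shape + 20 image types × 91), fused across k = 3 habitats into 5502
   subregional features.
6. **Feature selection** (`run_selection`): significance filter →
   correlation pruning → recursive elimination → mRMR → LASSO, all computed
   on training rows only, with strictly nested survivor sets.
7. **Models** (`train_model`, `compare_algorithms`): per-region signatures,
   a clinical logistic model, and a combined model, with six classifiers
   (logistic regression, RBF SVM, random forest, extremely randomized
   trees, depth-wise and leaf-wise gradient boosting).
8. **Evaluation** (`evaluate_model`, `delong_test`, `hosmer_lemeshow`,
   `decision_curve`, `shapley_attribution`, `nomogram_export`): DeLong AUC
   inference, threshold metrics at a training-frozen Youden point,
   calibration, decision curves, Shapley attribution, and a points-based
   nomogram.

`run_pipeline()` chains all stages on a generated cohort.

## The synthetic generator: what it emulates

Each patient carries one ellipsoidal lesion (diameter uniform on 8–30 mm)
on a native grid with anisotropic spacing 0.9×0.9×3.0 mm — realistic for
contrast T1 acquisitions with 3 mm slices, and coarse enough in z to
exercise the resampling stage. The lesion is partitioned into three
phenotype subregions by multiplicatively weighted Voronoi growth around
farthest-point seeds; the cell weights are iterated so realized volume
fractions track a per-patient Dirichlet draw centred on (0.5, 0.3, 0.2)
with concentration 20. Phenotypes have marginal intensities 100/145/190
(SD 10, i.e. 4.5 SD separation) and distinct texture correlation lengths
(0.8/1.6/2.5 mm, Gaussian-filtered white noise). Phenotype signals blend
over a ~0.5 mm transition at subregion interfaces (smoothed-indicator
weights): real habitats grade into one another, and the width is kept
below the analysis resolution so that voxel-wise Bayes classification on
intensity alone still recovers the generating labels with > 90% accuracy —
a property the test suite checks.

Outside the lesion, a peritumoral halo decays exponentially (amplitude 30,
e-folding width 3 mm) over a background of 40 ± 5. The image is multiplied
by a smooth random bias field (±20%, correlation length ~20 mm). Because
the field's correlation length is comparable to the volume, each patient
also receives a coherent global gain — exactly the scanner-gain
arbitrariness of real MR.

The response is drawn from a logistic model with four effects, documented
in `cohort_config()`: the phenotype-2 volume fraction (log-odds 8 per unit
fraction), a per-patient phenotype-2 intensity-contrast shift
(δ ~ N(0, 8) added to the phenotype mean; log-odds 0.12 per unit), male
gender (−0.8), and PNI (+0.08 per unit). The intercept is solved
numerically so the mean response probability equals the configured
prevalence (0.45). Both imaging effects are chosen so the habitat branch
carries signal *that habitat-level features can express*: the contrast
shift is read out directly by per-habitat first-order statistics, while
the volume fraction is visible to cluster-occupancy summaries.

**What the generator does not emulate:** anatomically realistic brain
structure, multi-lesion patients, scanner- and site-specific texture,
motion or susceptibility artefacts, and any coupling between response and
peritumoral texture. Passing tests therefore demonstrate that the
*machinery* is correct and that signals of the modelled kinds are
recovered end-to-end — not that the pipeline will reach any particular
performance on patient data.

## Habitat discovery: design notes

**The 19 local channels.** The window statistics are a robust quantile
profile: mean, median, min, max, range, P5/P10/P25/P40/P60/P75/P90/P95,
10%- and 25%-trimmed means, midhinge, midrange, RMS, and a 32-bin entropy.
Two design experiments drove this choice. First, moment statistics
(skewness, kurtosis) are extremely noisy in 125-voxel windows and
contribute only scatter. Second — and more consequential — spread-type
channels (SD, variance, MAD, gradient magnitude) respond to *interfaces*
between subregions rather than to the subregions themselves: with a
spread-heavy channel set, K-means dedicates clusters to boundary shells,
the Davies–Bouldin index then prefers k = 5 over the generating k = 3, and
voxel-truth recovery saturates near 0.75. With the quantile profile
(location-dominant, two dispersion channels), all three validity indices
agree at k = 3 on default cohorts and multi-seed assignment consistency
is ≥ 0.95. Channel count (19) and window (5×5×5 voxels at 1 mm) are fixed
by the framework being reproduced.

**Masked windows.** Neighbourhood statistics use in-mask voxels only.
With full windows, roughly half the voxels of a 20 mm lesion mix
background into their statistics and clustering degenerates to
rim-versus-core. Masked windows characterize boundary voxels by lesion
tissue.

**Pooled clustering and tissue calibration.** Clustering is population
level: voxels are pooled across training patients (a seeded subsample of
2000 per patient bounds memory) so labels are comparable across patients,
and the scaler and centers are frozen for validation/test assignment.
Pooling across patients only makes sense on a common intensity scale; MR
units are arbitrary per acquisition, and no bias-correction can identify a
patient-level gain from a single image (the in-mask DC level of the field
is unobservable). `preprocess_patient(normalize_intensity = "tissue")`
therefore calibrates each volume so the median normal-appearing background
(voxels > 6 mm from the lesion, beyond the halo) maps to a fixed
reference — the classic normal-tissue calibration, which leaves lesion
contrast untouched. The switch defaults to `"none"` at the function level;
`run_pipeline()` enables `"tissue"`.

**k selection.** For each k in 3..10, K-means (k-means++ seeding, best
inertia of 10 seeded restarts) is scored by Calinski–Harabasz (max),
Davies–Bouldin (min) and Silhouette (max); k* is the best mean rank, ties
to the smaller k. A `weak_structure` flag is raised when no k reaches
silhouette 0.5. Consistency is the mean over seed pairs of voxel agreement
after optimal label matching (Hungarian assignment on the k×k contingency
table) — a seed-stability measure, deliberately distinct from truth
recovery.

## Feature bank: inventory and numerics

The default inventory is pinned to the published counts: 1834 features per
region = 14 shape + 20 image types × 91, with 91 = 18 first-order +
22 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM, and 20 × 18 = 360
first-order features in total. The 20 image types are the original image,
8 single-level stationary-Haar wavelet sub-bands, Laplacian-of-Gaussian at
6 scales (0.5–5 mm), square, square-root, logarithm, exponential
transforms, and the gradient magnitude. (A 5-scale LoG bank would give 19
types and 1743 features; the printed totals require 20.) Habitat fusion
concatenates k = 3 per-habitat vectors into 5502 columns; a habitat absent
in a patient is imputed with zeros and flagged.

Discretization uses a fixed bin width of 25 on the original image and a
fixed bin count of 32 on derived images (whose scales differ from the
original), with a 256-level cap as a memory guard. GLCM/GLRLM aggregate
over the 13 unique 3D directions (summed, symmetric GLCM); GLSZM zones use
26-connectivity; NGTDM and GLDM use the in-region 26-neighbourhood, GLDM
dependence counting neighbours within gray-level tolerance 0 and indexing
dependence j = count + 1 so all sums are defined.

**Surface estimation.** Shape features come from the 0.5-isosurface of the
binary mask, triangulated by marching tetrahedra (a 6-tetrahedron cube
split: derivable without case tables, exact on axis-aligned faces).
Stair-stepping makes raw facet areas overestimate curved surfaces by up to
~30%, while smoothing the mask before meshing rounds away true edges. The
estimator used here keeps the sharp binary mesh (whose enclosed volume is
accurate) and *projects each facet onto the local surface orientation*
estimated from the gradient of a 0.8-voxel-smoothed indicator:
`A = Σ A_i |n̂_i · N̂_i|`. On phantoms this gives sphere areas within ~2%
(sphericity 0.965 at r = 5 mm), ellipsoid areas within ~0.3%, and a 10 mm
cube at ~6% below 600 mm² — sharp 90° edges are genuinely unrecoverable
from voxel data by any local estimator (a standard marching-cubes
reference is also ~6% low on that cube and ~8% high on the sphere).

## Selection, models, evaluation

The cascade order is fixed (significance → correlation → RFE → mRMR →
LASSO). Per feature, class-wise Shapiro–Wilk normality (α = 0.05) routes
to Welch's t-test or the Mann–Whitney U test; survivors need p < 0.05.
Correlation pruning removes, within each |r| ≥ 0.9 pair, the member with
the larger mean absolute correlation. RFE refits a ridge-penalized
logistic model and drops the smallest standardized coefficients down to
100 features; mRMR (F-statistic relevance, |Pearson| redundancy,
difference form) ranks 30; the LASSO (10-fold CV, deviance, λ-min by
default, 1-SE as an option) yields the final set, falling back to the mRMR
set with a `no_signal` flag when everything shrinks to zero. Intermediate
targets (100, 30) are configurable defaults chosen for the desk-scale
cohorts here.

Models: `lr` (GLM logistic), `svm` (RBF, probability outputs), `rf`
(random forest, 300 trees), `et` (extremely randomized trees), `xgb`
(depth-wise boosting, depth {2,3}, 100 rounds, η 0.1), `lgb` (leaf-wise
boosting via `grow_policy = "lossguide"`, {7,15} leaves). Grids are small
and tuned by seeded 5-fold CV AUC; fits are deterministic given the seed;
feature lists are frozen at fit time, and prediction on rows lacking a
required column is an error, never an imputation.

Evaluation: AUC is the Mann–Whitney concordance with 0.5 tie credit;
variance and paired tests come from DeLong's structural components
(cross-checked against pROC in the tests). Operating points use the
Youden-optimal threshold computed on the training cohort and frozen
elsewhere. Hosmer–Lemeshow uses decile-of-risk groups (degenerate groups
merged with a neighbour; both the statistic and its χ²(g−2) p-value are
reported). Decision curves use thresholds 0.01–0.99. Shapley attribution
is exact tree-path attribution (log-odds scale) for boosted models, the
closed additive form for logistic models, and permutation-sampling
elsewhere (each sampled permutation telescopes, so local accuracy is
exact). The nomogram scales each predictor's points by coefficient ×
range with the largest span at 100 points; the total-points-to-probability
map reconstructs the model exactly.

## Problem sizes and degenerate inputs

The shipped tests and the acceptance script run at desk scale: cohorts of
8–60 patients, lesions 8–30 mm, 2000 pooled voxels per patient with a
3000-voxel subsample for cluster-number selection, 10 K-means seeds, and
2000-replicate null simulations for the type-I-error checks. An
end-to-end 60-patient run (simulate through evaluation, seven signatures)
completes in a few minutes on one CPU.

Degenerate inputs are handled explicitly: non-positive intensities under
log-domain bias correction error (or shift with a warning), empty masks
and empty post-resampling masks error, zero-variance channels are dropped
with a warning and recorded, regions below 10 voxels produce an all-`NA`
feature row with a recorded reason, lymphocyte counts ≤ 0 yield a flagged
missing SIRI, complete separation in the clinical model falls back to a
ridge-penalized fit, and equidistant cluster assignment breaks ties to the
lowest label.

## Known limitations

* Statistical power at n = 60: with a 42/18 split, validation AUCs carry
  sampling noise of ~0.1, and a 1834-feature pure-noise region can show
  spurious cohort-wide associations. Comparisons between signatures on
  such cohorts are demonstrations of machinery, not powered experiments —
  even a model using the generating probabilities does not beat a noise
  region in every split.
* The bias-field estimator recovers the field's spatial pattern (r > 0.9
  against the generating field) but attenuates its amplitude; the
  downstream stages rely on tissue calibration, not on amplitude-exact
  correction.
* Sharp-edged shape phantoms (cubes) are measured ~6% low in surface area;
  curved, lesion-like shapes are accurate.
* Habitat truth recovery is bounded by partial-volume mixing at subregion
  interfaces and by 3 mm slice smearing; seed-to-seed assignment
  consistency (the stability metric reported) is near 1 even where truth
  recovery is ~0.8.
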