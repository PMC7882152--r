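---
title: "Methods: precuneus radiomics for covert hepatic encephalopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: precuneus radiomics for covert hepatic encephalopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Covert hepatic encephalopathy (CHE) is the mild, easily missed end of the
hepatic-encephalopathy spectrum in cirrhotic patients: cognition is impaired
(attention, psychomotor speed), but diagnosis currently requires
examiner-administered paper–pencil tests (number connection test A, digit
symbol test) whose scores are confounded by age and education. The precuneus
shows consistent structural and functional alterations in these patients, so
an objective image-based marker is plausible: compute quantitative radiomic
descriptors of the precuneus and its subregions from 3D T1-weighted MRI,
find the descriptors that separate CHE from non-CHE cirrhotic (nCHE)
subjects, and combine them with clinical risk factors (venous blood ammonia,
Child–Pugh stage) into a classifier and a clinician-usable nomogram.

This package implements that pipeline end to end and — because no patient
data are publicly deposited — ships a synthetic cohort generator with the
statistical structure the analysis assumes, so every stage is tested without
any download.

## Pipeline overview

1. **Imaging input** (`read_volume()`, `read_mask()`, `apply_mask()`):
   pre-aligned per-subject volumes and binary ROI masks (NIfTI-1). Masking
   is *selection*, not literal multiplication: background voxels are flagged
   absent and excluded from every statistic. Multiplying by the mask would
   conflate true zero intensities with background and corrupt the histogram
   features; this is a deliberate reading of the usual "point
   multiplication" phrasing. Masks below 27 voxels are rejected — texture
   matrices on smaller ROIs are not meaningful.
2. **Feature extraction** (`extract_roi_features()`): 423 features per ROI.
3. **Selection cascade** (`split_cohort()`, `select_features()`).
4. **Classifiers** (`fit_r_model()`, `fit_rc_model()`, `roc_analysis()`,
   `delong_test()`).
5. **Clinical outputs** (`build_nomogram()`, `calibration()`,
   `correlation_report()`).

The numbered scripts under `analysis/` drive these stages on the full-size
synthetic cohort and write summary tables under `results/`.

## The 423-feature space

Per ROI: 14 first-order histogram features, 22 gray-level co-occurrence
(GLCM) features and 11 gray-level run-length (GLRLM) features on the raw
masked ROI, plus the same 47 on each of 8 stationary Haar wavelet subbands
(LLL … HHH): 47 × (1 + 8) = 423; over the 10 precuneus ROIs, 4,230 columns.

Choices the feature definitions depend on (the literature rarely states
them; they are fixed here so every value is unambiguous and testable):

* **Discretization**: 32 equal-width bins over the per-ROI min–max. A fixed
  bin *count* is the standard radiomics choice when intensity units are
  arbitrary (normalized T1); it also makes every discretization-based
  feature exactly invariant under positive affine intensity rescaling
  (asserted in the tests).
* **Texture aggregation**: co-occurrences at lattice distance 1 along all
  13 unique 3D directions, each matrix symmetrized and normalized, features
  computed per direction and averaged over non-empty directions. Isotropic
  averaging removes any direction-ordering ambiguity.
* **Runs** are maximal same-level voxel sequences along a direction and are
  broken by mask boundaries — a hole splits a run, it is never bridged.
* **Degenerate conventions**: on a single-level (constant) ROI, GLCM
  correlation, IMC1 and IMC2 are defined 0 (their marginal entropies or
  variances vanish); first-order skewness and kurtosis of a constant ROI
  are 0. Variance is the population (1/N) form; kurtosis is excess
  kurtosis; entropies are in bits.
* **Wavelet transform**: one-level *stationary* (undecimated) Haar
  transform with periodic boundary handling. The Haar filter is the
  shortest available, minimizing boundary effects on small ROIs, and the
  undecimated form keeps every subband on the original grid so the original
  mask applies unchanged — no mask-resampling rule is needed. Subband
  letters follow axis order (x, y, z).
* **Naming**: `<roi>_<family>_<feature>[_<subband>]`, e.g.
  `right_Lc1_intensity_Median_HLL`, so the field's usual labels ("right
  Lc1, Median, HLL") map 1:1 onto columns.

Texture correctness is established against an independent brute-force
pair/run enumerator (plain triple loops) on random 5×5×5 masked ROIs, to
1e-10.

## Selection cascade

* **Split**: stratified 7:3 — `floor(0.7 · n_class)` per class to training
  (a 54/52 cohort gives 73 = 37 + 36 training, 33 = 17 + 16 testing);
  the permutation is a function of the seed only.
* **Univariate filter**: per feature, Shapiro–Wilk within each group; only
  if *both* groups look normal (p ≥ 0.05) is the pooled-variance t-test
  used, otherwise the Mann–Whitney U (normal approximation, tie and
  continuity corrected). Keep at p < 0.05, no multiplicity correction.
  The both-groups gate is the conservative, symmetric reading of
  "check normality first". Features constant across the pooled training set
  are excluded with a logged reason — neither test is defined for them.
* **Redundancy**: features scanned in order of ascending univariate p; a
  feature is admitted only if |Spearman ρ| ≤ 0.9 against every
  already-admitted feature. Keeping the smaller-p member of a correlated
  pair is deterministic and retains the most discriminative representative.
* **LASSO**: the squared-error objective
  (1/n) Σ (yᵢ − β₀ − xᵢβ)² + λ‖β‖₁ on 0/1 labels, minimized by cyclic
  coordinate descent with an active-set strategy, features z-scored
  (population sd) on training statistics. The λ path has 100 log-spaced
  points from λ_max = maxⱼ |(2/n) Σ xᵢⱼ(yᵢ − ȳ)| (the smallest all-zero λ,
  by the subgradient condition) down four decades when n > p, or two
  decades in the overparameterized p ≥ n regime where smaller λ values
  only interpolate (the same floor convention the standard solvers use). λ_min is the minimum
  mean squared prediction error under stratified 10-fold CV — the minimum
  rule, not the 1-SE rule, matching the "minimum criteria" convention.
  The squared-error form (rather than logistic deviance) is used because
  that is the objective this analysis tradition actually prints; the
  classification model proper is refit separately. The objective is
  asserted non-increasing after every sweep, and a failure to converge is
  an error with diagnostics — never a silent partial fit.

Numerical notes: coordinate updates use the exact soft-threshold solution;
convergence is declared when a full sweep changes no coefficient by more
than 1e-6 or improves the objective by less than a 1e-10 relative margin.
On orthonormal designs the solution equals soft-thresholding of the OLS
coefficients (tested to 1e-8); general solutions agree with an independent
solver to ~1e-5 (its λ is half ours under the 1/(2n) convention).

## Classifiers and evaluation

* **Radscore** = β₀ + Σ βᵢxᵢ with the LASSO coefficients at λ_min on
  standardized features; β₀ is the LASSO intercept (the training label
  mean). The R model is an *unpenalized* logistic refit on the signature
  features; the R-C model is logistic on exactly {Radscore, NH₃,
  Child–Pugh (ordinal 1/2/3)}. Fitting both objects — shrunken scores for
  the signature, maximum-likelihood refits for classification — is the
  reading that reconciles how the two are usually reported.
* **Evaluation**: empirical ROC; AUC as the Mann–Whitney concordance
  (ties ½); 95% CI from the DeLong variance on the logit scale (clipped to
  [0, 1] — the transform produces the asymmetric intervals typical of
  published tables). Operating threshold: Youden maximum on *training*,
  applied unchanged to testing, CHE positive; this is what produces
  testing sensitivities of 1.0 with specificity below 1.0. Model
  comparison: paired DeLong z-test on the structural components, p = 1 by
  convention for degenerate variance.
* **Perfect separation** (common in small synthetic cohorts) is flagged
  with a warning; evaluation proceeds on the fitted scores, whose ranking
  (hence ROC) is stable even when the coefficients are not.

## Nomogram, calibration, correlations

The nomogram maps each R-C predictor to 0–100 points,
points_j(v) = 100·β_j(v − ref_j)/max_k |β_k|·range_k, with ref_j the range
endpoint giving 0 points; total points map to probability through the
logistic inverse of the reconstructed linear predictor. Reading any subject
off the nomogram reproduces the model probability to well under 0.01 — a
construction identity asserted for every synthetic subject.

Calibration uses deciles of predicted probability (quantile cut, ties to
the lower bin), the Hosmer–Lemeshow statistic Σ (O−E)²/(E(1−E/n)) on g − 2
degrees of freedom (g = 10 by default; degenerate bins are merged with a
neighbour and the df reduced). Under a correctly specified model the test
holds its 5% level and its p-values are approximately uniform (checked by
simulation).

Correlations between the signature features (+ Radscore) and NCT-A, DST,
NH₃, Child–Pugh (ordinal), age, sex (0/1) and education are Spearman ρ with
t-approximation p-values, no multiplicity correction. Real-data correlation
magnitudes are *not* reproduction targets — the generator only ties
cognition to class, so planted imaging effects produce sign-consistent
correlations (features lower in CHE correlate positively with DST, which is
lower in CHE, and negatively with NCT-A).

## The synthetic cohort generator

What it emulates: two-class cohorts (defaults 54 CHE / 52 nCHE) of
per-subject, per-ROI volumes plus a clinical table.

* **Volumes** are Gaussian random fields: unit white noise convolved with
  an isotropic Gaussian kernel (default length 1.5 voxels, truncated at
  3σ, periodic), renormalized to unit pointwise variance, then placed at
  the class-conditional mean and scale (baseline 100 ± 10 in arbitrary
  normalized-T1 units). In the effect ROIs (defaults: right PEp and right
  Lc1 — the regions a real signature concentrates in) the CHE class gets a
  +5 mean shift, a 1.5× variance ratio and a 1.4× smoothing-length ratio.
  Smoothing length is the texture knob: GLCM/GLRLM features respond
  monotonically to spatial autocorrelation (asserted as a property test).
  This is the simplest generator whose three parameters map interpretably
  onto the four signature feature types (Variance, Median, GLN, IMC1).
  The effect sizes are moderate-but-detectable choices for a cohort of
  this size; they were fixed once when the generator was written.
* **Masks** are axis-aligned ellipsoids inscribed in the grid (semi-axes
  90% of each half-extent): non-box geometry exercises run handling across
  oblique mask boundaries. Default volumes are 24³ voxels at 1 mm —
  subregion-scale ROIs (~4,700 voxels) that keep a full cohort extraction
  tractable on one CPU.
* **Clinical covariates** are drawn class-conditionally from distributions
  parameterized by the training-set summaries typical of HBV-cirrhosis CHE
  cohorts: NH₃ log-normal (positive support) moment-matched to
  57.43 ± 44.45 (CHE) vs 21.36 ± 12.13 (nCHE) μmol/L; Child–Pugh
  categorical with probabilities 8/13/16 ÷ 37 (CHE) vs 21/12/3 ÷ 36
  (nCHE); NCT-A, DST, age and education normal truncated at zero; sex
  Bernoulli. Only means/sds and counts are matched — higher moments are
  free choices of the generator, not claims about real data.
* **Reproducibility**: per-subject streams derive from the master seed by a
  fixed counter hash (subject index × 1000 + ROI index); cohorts
  regenerate bit-identically under the same seed, and the whole pipeline
  is deterministic given the single `master_seed` of `pipeline_config()`.

What it does **not** emulate: anatomy, skull, registration error, scanner
noise spectra, inter-ROI correlation, or any coupling between imaging and
clinical covariates beyond the shared class label. Passing tests therefore
show that the *machinery* is correct and calibrated under known truth —
not that the published real-data effect sizes are recoverable; those
numbers cannot be reproduced without the original cohort.

## Problem sizes used in the tests and acceptance script

Unit and property tests run on deliberately small objects: 5×5×5 ROIs for
the brute-force texture oracles (50 cases), 12³–16³ volumes for
imaging-level properties, 200-simulation calibration suites for the
5%-level checks, and a 20-seed recovery suite at the study's training size
(4 planted 2-sd features among 100 nulls, n = 73). The end-to-end pipeline
demonstrations use reduced cohorts (8–12 subjects per class, 2 ROIs);
`analysis/` runs the full 54/52 × 10-ROI cohort. These sizes are the
package's own trade-off between statistical resolution and a test suite a
maintainer will actually run.

## Known limitations

* Feature lists are anchored to the four named signature feature types
  plus standard first-order/GLCM/GLRLM sets; no shape/morphology or
  Laplacian-of-Gaussian families, no 2D slice-wise mode, and no claim of
  IBSI certification.
* The LASSO solves the printed squared-error objective; an elastic net or
  logistic-deviance variant is out of scope.
* The stationary wavelet transform is Haar-only and one-level.
* Registration, skull stripping and atlas reslicing are upstream of the
  package: volumes and masks must arrive on a common grid.
* Hosmer–Lemeshow bin count and df follow the standard g = 10, g − 2
  convention; published real-data HL p-values are not recoverable and are
  not targets.
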