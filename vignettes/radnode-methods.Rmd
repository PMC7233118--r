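---
title: "Predicting lymph-node status after neoadjuvant therapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lymph-node status after neoadjuvant therapy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

After neoadjuvant therapy for locally advanced rectal cancer, organ-sparing
strategies hinge on knowing whether regional lymph nodes still harbor
metastases (LNM+). Radiologists restage nodes on MRI (the ymrN stage), but
morphology-based nodal reads are weak: sensitivity near 56% and specificity
near 71% are typical. `radnode` implements a radiomics pipeline that
predicts pathological node status from texture and intensity features of
the primary tumor across four MR sequences (T1w, T2w, CE-T1w, ADC map),
combines the resulting radiomic signature with the radiologist's ymrT/ymrN
stages in a logistic model, and evaluates everything with the standard
clinical-prediction toolkit.

Real cohorts of this kind are private; the package therefore ships a synthetic
cohort generator that reproduces the *statistical structure* the analysis
assumes, so that every stage of the pipeline is testable end to end.

## Pipeline

1. **Feature extraction** (`extract_feature_table()`): per sequence, 264
   features — 4 filters (original image and Laplacian-of-Gaussian at
   sigma = 1, 2, 3 px, named `orig`/`LoG1`/`LoG2`/`LoG3`) times 66
   statistics (24 first-order, 26 gray-level co-occurrence, 16 size-zone) —
   computed on the single 2D slice inside the tumor mask, 1056 features per
   patient in total. Intensities are discretized into 32 equal-width bins
   between the ROI minimum and maximum, which makes the texture features
   invariant to any monotone affine intensity rescaling. GLCMs use the four
   distance-1 directions, symmetrized and averaged; size zones use
   8-connectivity. These are conventional 2D radiomics settings; published analyses rarely disclose their exact
   roster behind such counts, so the registry here is a documented default
   whose per-sequence count — the reproducible part of the contract — is
   exactly 264.
2. **Normalization** (`fit_normalizer()`/`apply_normalizer()`): per-feature
   min-max scaling to [0, 1], with the minimum and maximum taken from the
   primary cohort only. Validation values may fall outside [0, 1]; they are
   deliberately not clipped.
3. **Three-step selection** (`select_features()`): a two-sided Wilcoxon
   rank-sum screen keeping features with p <= 0.1 (inclusive); Spearman
   redundancy pruning that, for every pair with |rho| > 0.9, drops the
   member with the larger screening p-value; and an L1-penalized logistic
   path whose penalty is chosen by the one-standard-error rule under
   10-fold label-stratified cross-validation (binomial deviance loss,
   seed-fixed folds, no re-standardization since features are already on
   [0, 1]).
4. **Modeling** (`fit_signature_model()`, `fit_combined_model()`): the
   radiomic signature is the linear predictor of a maximum-likelihood
   logistic fit on the selected features; the predicted probability is its
   logistic transform. The combined model enters the raw signature together
   with numeric ymrT and ymrN scores; the clinical model omits the
   signature. The combined model is exported as a nomogram whose
   total-points-to-probability map is algebraically exact.
5. **Evaluation** (`evaluate_model()` and friends): AUC as the Mann-Whitney
   pair statistic with DeLong variance (CI and paired test), Youden cutoff,
   Clopper-Pearson intervals for sensitivity/specificity/PPV/NPV/accuracy,
   McNemar (exact below 25 discordant pairs), continuous net
   reclassification improvement, Hosmer-Lemeshow calibration, decision
   curves, Cohen's kappa, and ymrT1-2/ymrT3-4 stratified reports. Cutoffs
   are always derived in the primary cohort (per subgroup for the
   stratified reports) and applied unchanged to validation data.

## What the synthetic generator emulates

Each patient carries four co-registered 64 x 64 images sharing one
elliptical tumor mask (semi-axes between 1/8 and 1/3 of the image side).
Images are stationary Gaussian random fields; inside the mask the field's
correlation length grows by `texture_effect` pixels and its mean by
`intensity_effect` standard deviations for LNM+ patients. These two knobs
were chosen as the minimal mechanisms detectable by, respectively, the
co-occurrence/size-zone families and the first-order family — the two
families this kind of nodal-restaging signature typically selects. The T1w channel has
both effects pinned to zero, emulating an uninformative sequence.

Cohort structure: exactly `round(n * prevalence)` positives (defaults
n = 391, prevalence = 87/391), a single frozen 2:1 primary:validation
split, a simulated radiologist whose ymrN read has sensitivity 0.563 and
specificity 0.707 against the true label, a ymrT stage positively
associated with the label, and sex/age/CEA/radiation drawn independently of
it (so univariate screens should reject them). Clinical covariates are
linked to the label through their stated conditional probabilities only; no
joint dependence beyond that is modeled.

Default effect sizes are `texture_effect = 0.05` and
`intensity_effect = 0.08`. They were fixed once so that the full pipeline's
validation AUC lands broadly in the 0.7-0.9 range at the default cohort
size — the discrimination regime a realistic rectal-MRI radiomics signature
occupies — rather than in the saturated regime where every run separates
perfectly. Property tests use two other regimes: a *strong* setting
(texture 1.0, intensity 0.6) where signal recovery is essentially
guaranteed, and a *zero* setting where the pipeline should find nothing.

What the generator does **not** emulate: MR physics and sequence-specific
contrast, ADC computation from DWI, registration error between sequences,
inter-rater mask variability, and non-elliptical tumor shapes. Passing
tests therefore demonstrate that the pipeline recovers the kind of signal
it assumes, on data satisfying its assumptions — not that the signature
generalizes to scanner data.

## Numerical choices and degenerate inputs

* Discretization is right-closed on the top bin; a constant ROI maps to
  level 1 everywhere, with first-order skewness/kurtosis and entropy
  defined as 0.
* The LoG kernel is scale-normalized (multiplied by sigma^2), explicitly
  zero-mean (so constants map to exactly 0), and applied under reflection
  padding.
* GLCM correlation is defined as 0 when a marginal is degenerate; the
  information-measure features guard their logs against empty cells.
* Features constant in the primary cohort normalize to 0 with a warning.
* The Wilcoxon screen uses the exact distribution when both groups have at
  most 25 patients and no ties, otherwise the midrank normal approximation
  with tie correction and no continuity correction.
* Spearman pruning processes pairs in descending |rho| with lexicographic
  tie-breaks, skipping pairs with an already-dropped member; exact p-value
  ties drop the lexicographically later name. The survivor set is therefore
  deterministic, which matters when correlation graphs form chains.
* Logistic fits converge to 1e-8 or error; under (quasi-)separation the
  fitting functions error with advice, and the pipeline uses the documented
  fallback of a tiny (1e-6) ridge penalty. If the LASSO selects nothing the
  signature degrades honestly to an intercept-only model (constant
  signature, AUC 0.5).
* The Youden search scans midpoints of consecutive distinct scores and
  breaks ties toward the higher threshold (higher specificity).
* McNemar switches from the exact binomial to the continuity-corrected
  chi-square at 25 discordant pairs.
* The NRI is the continuous (category-free) variant; no category bins are
  defined anywhere in the pipeline, so the category-free variant is the
  only coherent choice.
* Hosmer-Lemeshow uses risk-decile grouping, chi-square with g - 2 degrees
  of freedom (appropriate for fitted probabilities), and merges tied decile
  boundaries with a warning; the pipeline reduces the group count on small
  validation cohorts (groups of at least ~5 patients).
* Proportion CIs are Clopper-Pearson throughout. Published restaging reports often print internally
  inconsistent intervals, so the package documents its own method rather
  than imitating any particular one.
* The nomogram reference value of each variable is its minimal-risk end
  (the range minimum for positive coefficients, maximum for negative ones),
  which makes total points an increasing affine function of the linear
  predictor and the probability axis exact to machine precision.

## Open design points, resolved

* **ymrT/ymrN coding.** Both stages enter models as numeric scores (one OR
  per stage unit), matching the single-row treatment such analyses report
  (one odds ratio per stage variable);
  dummy-coded stage blocks are a deliberate non-feature.
* **Signature in the combined model.** The signature enters as the raw
  linear predictor, not its probability transform — the natural choice when the
  multivariate intercept is to absorb the signature model's intercept.
* **Subgroup cutoffs.** Stratified reports re-derive the Youden cutoff
  within the primary-cohort subgroup and apply it to the matching
  validation subgroup.
* **Per-sequence delineation.** One shared mask per patient (perfect
  co-registration); modeling per-sequence delineation disagreement (the ICC
  range a real dual-reader study would report) is out of scope, though
  `feature_agreement_icc()` implements the ICC(2,1) computation itself.

## Problem sizes used in the test-suite

Oracle-equivalence checks run on 100 random 16 x 16 images; statistical
null checks use 20 replicates of 40 x 150 feature tables (Wilcoxon), 300-400
replicates of n = 200 calibration draws (Hosmer-Lemeshow), and n = 10,000
draws (kappa); parameter recovery uses 100 cohorts of n = 2,000; the
end-to-end signal-recovery properties use 20 strong-effect and 20
zero-effect cohorts of 391 patients at the default image size. These sizes
keep Monte-Carlo error comfortably below the asserted tolerances.

## Known limitations

2D, single-slice, intensity-and-texture radiomics only: no shape or wavelet
features, no 3D aggregation, no scanner harmonization, no DICOM ingestion.
The synthetic cohort validates software correctness and statistical
behavior, not clinical performance; the headline numbers of any real
application must come from real, properly partitioned patient data.
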