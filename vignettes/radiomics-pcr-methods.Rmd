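---
title: "Methods: an MRI radiomics pipeline for pCR prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an MRI radiomics pipeline for pCR prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`radiopcr` implements a complete radiomics analysis chain for predicting
pathological complete response (pCR) to neoadjuvant chemoradiotherapy from
pretreatment T2-weighted MRI of locally advanced cervical cancer. This
vignette is the package's account of the science behind each stage: the
procedure and its assumptions, the parameters that matter, the numerical
conventions, and what the synthetic phantoms do and do not demonstrate.

## The prediction problem

The outcome is binary: pCR (no residual tumour in the surgical specimen,
the positive class) versus residual disease (microscopic pR1 or macroscopic
pR2, both mapped to the negative class). The predictors are quantitative
descriptors of the gross tumour volume (GTV) contoured on axial
T2-weighted images: its intensity distribution, texture, geometric
complexity and shape. The working hypothesis of radiomics is that
intratumoural heterogeneity visible at MRI resolution carries prognostic
information that a radiologist's categorical read does not.

## Imaging stages

**Resampling.** Acquisition protocols differ between institutions, so all
slices are resampled in-plane to a common 0.548 × 0.548 mm² grid (bilinear
for intensities, linear + 0.5-threshold for masks). The slice axis is left
untouched: slice thickness varies across protocols and interpolating
through it would fabricate detail. Interpolation uses the nested-lerp form,
which preserves constant regions exactly and is monotone. These two choices
(2D-only, bilinear/threshold) are the package's own; the source design
states neither.

**LoG bank.** The Laplacian of Gaussian is a band-pass filter that responds
to intensity variation at scale σ. The bank sweeps σ from 0 to 4.2 mm in
0.35 mm steps (13 scales); σ is specified in millimetres and converted to
pixels through the voxel spacing, so responses are comparable across
resolutions. σ = 0 denotes the unfiltered image — the raw-image moments are
legitimate members of the bank. The kernel samples the analytic 2D LoG at
pixel-centre offsets out to 4σ and is recentred to zero sum, so a constant
image maps exactly to zero; convolution is per axial slice with
edge-replicated boundaries, computed by FFT (the direct-convolution oracle
in the test suite pins the numerics).

**IB filter.** ROI grey levels are normalised so the 1st and 99th ROI
percentiles map to 0 and 1 (clipping outside), then voxel subpopulations
are taken between every pair of thresholds drawn from 0%, 10%, …, 100% of
the maximum (lower < upper; 55 pairs). Both interval ends are closed, so a
voxel sitting exactly on a boundary belongs to both adjacent pairs — a
deterministic, documented convention; the alternative half-open choice
changes results only on measure-zero boundaries. An empty subpopulation is
a legal outcome: features computed on it return `NA`.

## Feature families

First-order statistics (18 of them: moments with population conventions —
variance over n, Pearson kurtosis so a normal gives 3 — plus quantiles,
energy, histogram entropy/uniformity over 64 fixed-width bins) are computed
on every LoG scale within the ROI. Texture, fractal and morphology families
are computed per IB subpopulation:

* **GLCM** features discretise the normalised intensities into 32 equal
  bins over [0, 1], accumulate symmetric co-occurrences over the four
  planar directions at distance 1 pixel (summed across directions and
  slices before normalising), and report contrast, correlation, energy,
  homogeneity, entropy, cluster shade and cluster prominence. Cluster shade
  Σᵢⱼ(i + j − μᵢ − μⱼ)³ p(i,j) is the third co-occurrence moment: it is
  zero for any distribution symmetric about its mean grey level and flips
  sign under intensity negation, properties the test suite verifies by
  brute force. Bin count, distance and direction handling are exposed in
  `bank_config()`; none is fixed by the source design, so common
  IBSI-compatible defaults were chosen once.
* **Fractal** features estimate the box-counting dimension per axial slice
  (least-squares slope of log N(ε) against log 1/ε over dyadic box sizes
  anchored at the mask bounding box) and report the mean, SD and maximum
  over slices. A filled square yields 2, a line 1, an isolated pixel 0 —
  exactly, by construction of the dyadic schedule.
* **Morphology** reports physical volume, an exposed-face surface proxy,
  the sphericity index π^(1/3)(6V)^(2/3)/A, the maximum in-plane diameter
  (convex-hull pixel-centre distance) and the number of 8-connected planar
  components. Connectivity is not defined by the source design;
  8-connectivity per slice is the package's choice.

With the default bank the census is 13·18 + 55·(7 + 3 + 5) = 1059 features.
The census is configuration arithmetic, logged per run — the original
study's census (1889) is not enumerable from its text, so no attempt is
made to match it. GLCM and fractal features require at least 8
subpopulation voxels (below that, `NA`); features missing in more than 20%
of cases are dropped before selection and the rest are median-imputed.

## Feature selection

The cohort is split into 8 outcome-stratified folds (stratification
prevents folds without positives at ~40% prevalence; the assignment deals
each shuffled class into the currently smallest fold, so fold sizes differ
by at most one). Each feature is tested on each of the 8 leave-one-fold-out
subsets; a feature *votes* when p < 0.05, and survives with ≥ 5 of 8 votes.
The univariate test is Welch's t when both classes have at least 8 cases
and both pass Shapiro–Wilk at α = 0.05, otherwise the Wilcoxon–Mann–Whitney
test (exact in small tie-free samples, tie-corrected normal approximation
otherwise). The small-sample floor matters: normality testing below n = 8
is uninformative, so tiny classes default to the rank test.

Survivors are pruned greedily: candidates are visited by ascending median
p-value (ties: more votes, then lexicographic id) and accepted only if
|Pearson r| < 0.6 against every feature already accepted. Absolute
correlation is used deliberately — an anti-correlated duplicate is exactly
as redundant as a correlated one.

No multiple-testing correction is applied, and selection runs **once on
the full cohort, before model cross-validation**. That is the design being
re-implemented, and it has a known consequence: on weak or null signal the
subsequent cross-validated AUCs are optimistically biased, because the
held-out folds participated in choosing the features. The package
documents this rather than silently repairing it; the test suite measures
it directly by running the full pipeline on seeded null cohorts, where the
winner's mean CV AUC sits well above chance even though no feature carries
real signal. Any honest reading of the pipeline's CV AUC must keep this
selection bias in mind.

## Model selection and evaluation

Fifteen classifiers are compared under 3 repeats of stratified 8-fold CV
(fresh partitions per repeat, shared across classifiers so means are
comparable), giving 24 held-out ROC AUCs per classifier; the winner has the
highest mean AUC, ties resolving to the lower sample SD (n − 1 over the 24
values) and then roster order. Every classifier must emit class-1
probabilities; PLS, whose native output is a latent-score projection, is
wrapped with a logistic (Platt) calibration fitted on the training folds.
The reference random forest uses ntree = 500 and mtry = floor(√p); the
grid- and random-search variants tune mtry over 10 candidates by OOB error
on the training folds only. Two roster members are implemented in-package
(nearest shrunken centroids with internally cross-validated shrinkage, and
diagonal shrinkage discriminant analysis with variances shrunk 25% toward
their mean); the rest delegate to standard implementations (rpart, xgboost,
mclust EDDA, caret's knn3, glm, e1071 naive Bayes/SVM, nnet, glmnet ridge,
mixOmics PLS-DA, randomForest). A classifier failing on a fold contributes
a missing AUC with a warning, never an imputed value.

ROC curves follow the convention *predict positive when score ≥ threshold*;
AUC is the trapezoidal integral, which equals the Mann–Whitney statistic
with the ½ tie convention (the suite checks this exhaustively on small
vectors). The operating point maximises the Youden index
J = sensitivity + specificity − 1 over the curve's points, endpoints
included (so the optimum is never negative); ties resolve toward the higher,
more specific threshold.

## The synthetic phantoms

Because no patient images are distributed, the generator produces seeded
two-class cohorts of ellipsoidal lesions (default geometry: 10 mm radius on
a 36 × 36 × 10 grid of 1.096 × 1.096 × 3 mm voxels, so the 0.548 mm
resampling stage is genuinely exercised; default cohort 183 cases with
74/183 positive prevalence, matching the merged two-institution cohort).
Intra-lesion texture is a Gaussian random field — white noise smoothed per
slice at a class-specific correlation length — passed through the monotone
transform (exp(s·x) − 1)/s whose shape parameter s controls skewness and
tail weight, then scaled onto a bright-lesion/dark-background intensity
model with additive Gaussian noise. Classes differing in correlation length
move GLCM and fractal features; classes differing in s move the first-order
moments; equal parameter sets define an exact null. All randomness flows
from one integer seed.

The phantoms emulate *statistical* texture contrast, not MRI physics: no
bias fields, no acquisition noise spectra, no anatomical context, no
inter-scanner variation, and identical lesion geometry across classes (so
morphology is uninformative by construction). Passing tests therefore
demonstrate that the pipeline's machinery is correct and calibrated — null
p-values uniform, planted effects recovered, AUC ordering monotone in
effect size — not that any particular AUC is attainable on real patients.
The class effect sizes are free knobs: nothing in the source design
quantifies how responder and non-responder textures differ, so defaults
were set once to give a clearly separable cohort and are not calibrated to
the study.

## Problem sizes and numerical conventions

The test suite and acceptance script run at deliberately modest sizes
chosen once: selection calibration and recovery use 500-feature tables at
n = 180–200 over 20 seeded replicates; the roster-wide modelling checks use
n = 120–160; end-to-end imaging runs use cohorts of ~24 phantoms with a
reduced IB level step. These sizes keep every Monte-Carlo tolerance
meaningful while the whole suite completes on a single CPU in minutes.
Other conventions worth knowing: constant features return p = 1; degenerate
normalisation (1st = 99th percentile) is an error, as is a ROI that
vanishes under resampling; an empty pruned set aborts the pipeline with a
stage-tagged error rather than training on nothing; and GLCM correlation of
a single-level region is defined as 1.

## Known limitations

* Selection-before-CV bias, discussed above: cross-validated AUCs from
  `run_pipeline()` are not unbiased generalisation estimates.
* The feature census is configuration-defined; it does not reproduce the
  original 1889-feature roster, which is not recoverable from its
  description.
* The classifier roster maps each method to its closest standard
  implementation; hyperparameter defaults beyond the reference random
  forest are implementation defaults, documented per key in
  `classifier_roster()`.
* Reported sensitivity/specificity at the Youden point of the final model
  are training-set quantities, inheriting resubstitution optimism on top
  of the selection bias.
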