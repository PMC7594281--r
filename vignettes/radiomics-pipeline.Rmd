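---
title: "An MRI radiomics pipeline for lipomatous soft-tissue tumors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An MRI radiomics pipeline for lipomatous soft-tissue tumors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Benign lipomas and atypical lipomatous tumors / well-differentiated
liposarcomas (ALT/WDL) overlap heavily on conventional MRI, yet their
management differs radically: lipomas can be watched, ALT/WDL must be
resected completely. `lipomics` implements a radiomics pipeline for this
discrimination task on a single 2D slice of a contrast-enhanced,
fat-suppressed T1-weighted image: an 87-feature radiome is extracted from
the tumor mask, features are screened for inter-observer reproducibility
and class relevancy, and a linear support-vector machine predicts
malignancy. Because no patient images ship with the package, a synthetic
phantom generator reproduces the statistical structure the analysis relies
on, so every stage is exercised and tested end to end.

## Pipeline overview

1. **Slice choice** — on multi-slice masks, the analysis slice is the one
   with the largest maximum Feret diameter (the longest tumor diameter,
   measured in mm between boundary pixel centers).
2. **Morphology** — 6 size and 5 shape features from the binary mask.
3. **Intensity distribution** — 14 first-order statistics of the raw
   masked intensities, two of them from a 256-bin histogram.
4. **Image-domain texture** — the masked intensities are discretized with
   an equal-probability algorithm at 8, 16, 24, 32, 40, 48 and 64 gray
   levels; at each level four texture matrices are built (GLCM, GLRLM,
   GLSZM, NGTDM) and 52 features are computed, averaged over 4 directions
   (GLCM/GLRLM) and then over the 7 levels.
5. **Frequency-domain texture** — a Gabor bank with 5 scales (minimal
   wavelength 3 px, sqrt(2) progression), 6 orientations and 1-octave
   bandwidth; 10 features (per-scale orientation-averaged mean and
   variance of the response magnitude).
6. **Reproducibility** — per feature, Pearson r, R^2 and Spearman rho
   between two observers' extractions; reproducible means r > 0.8.
7. **Discretization stability** — per feature, the coefficient of
   variation (CV) across the 7 levels, averaged over 10 randomly drawn
   subjects per class; CV <= 5% counts as no variation, 5-25% acceptable,
   > 25% unacceptable.
8. **Selection and classification** — keep features with pooled t-test
   p < 0.2 *and* Pearson r > 0.8; z-score with training statistics; train a
   linear soft-margin SVM (C = 1) by sequential minimal optimization on a
   stratified 75/25 holdout; report sensitivity, specificity, PPV, NPV and
   accuracy with unclipped Wald 95% CIs, plus the rank-statistic AUROC.

```{r}
library(lipomics)
res <- run_pipeline(cohort_spec(seed = 1))
res$evaluation$metrics
```

## Models and conventions

### Equal-probability quantization

Decision thresholds are the k/L-quantiles (k = 1..L-1) of the masked
intensity multiset, computed as order statistics (quantile type 1, no
interpolation). Bins are right-closed, so a pixel's level is
`1 + #{thresholds < value}`. Ties are never split: equal intensities always
share a level, even when that unbalances the bins — mapping equal values to
different levels would make texture features depend on pixel ordering. On
continuous input the bin counts differ by at most 1 (a tested property). A
constant region degenerates to a single level and raises a warning flag.

### Texture matrices

* **GLCM**: symmetric co-occurrence of level pairs at 1-pixel offset in 4
  directions (0, 45, 90, 135 degrees); pairs crossing the mask boundary are
  excluded; normalized to sum 1. 21 features (Haralick plus the normalized
  inverse-difference family and inverse variance).
* **GLRLM**: maximal collinear same-level runs inside the mask, per
  direction; 13 features; run percentage divides by the masked pixel
  count.
* **GLSZM**: connected same-level zones under full-neighborhood adjacency.
  The protocol's "26-pixel connectivity" is a 3D notion; on a 2D slice the
  full neighborhood is 8-connected, which is what the package uses.
* **NGTDM**: per level, the count `n_i` of masked pixels with at least one
  masked 8-neighbor and the sum `s_i` of absolute differences between the
  level and the mean of the pixel's masked neighbors; 5 Amadasun-King
  features.

Direction handling: features are computed **per direction and then
averaged** (not matrices summed) — the dominant convention in the classical
texture literature. A direction without a single valid pair or run (for
example a 1-pixel-wide bar at 0 degrees) is dropped from that average; it
is an error only if all four directions are empty.

Numerical conventions, all tested: logarithms are base 2 with
`0 * log 0 = 0`; correlation and both information measures of correlation
are defined as 0 when a marginal SD (or entropy) vanishes; NGTDM
denominators that can vanish are guarded by epsilon = 1e-6, so a constant
region has coarseness 1e6 by convention and contrast 0; population (not
sample) variance is used throughout the matrix features. Sum variance is
centered on sum average; difference variance is centered on the mean of the
difference distribution. These follow the IBSI-consistent form of the
classical definitions; where the historical literature offers variants
(e.g. GLN normalization) the package pins the IBSI-consistent one.

### Morphology and intensity

Masks are grids of unit pixel squares; distances are between pixel centers
and scale with the pixel spacing in mm. The perimeter is the length of the
outer marching-squares contour at level 0.5 — stable enough that a
digitized disc has circularity near (and never meaningfully above) 1. Major
and minor axis lengths come from the second central moments with the 1/12
pixel-square correction (regionprops convention). Solidity divides the
pixel count by the pixel count of the convex image (the grid fill of the
convex hull of pixel centers); since the mask is a subset of its convex
image, solidity never exceeds 1. The intensity histogram spans
`[min, max]` of the masked values with 256 equal-width bins and a
right-closed last bin; the per-subject range is used because the protocol
prescribes no normalization of intensities. Skewness is the Fisher moment
ratio, kurtosis the Pearson ratio (normal = 3), both with population
moments.

### Gabor bank

Wavelengths follow `3 * sqrt(2)^(s-1)` px from the stated minimum of 3; the
Gaussian envelope is isotropic with sigma set by the 1-octave bandwidth and
truncated at 3 sigma; kernels are DC-corrected by subtracting a scaled
envelope so that a constant image responds with (numerically) zero. The
protocol does not name its 10 Gabor statistics; the package fixes them as
the per-scale orientation-averaged mean and variance of the response
magnitude over masked pixels, matching the printed count and mirroring the
direction-averaging of the matrix features. Filtering uses reflect padding
and exploits the separability of the isotropic-envelope Gabor kernel into
two 1D complex kernels (a compiled routine); a direct 2D convolution oracle
verifies the factorization in the tests.

### Reproducibility, CV and selection

R^2 is the square of Pearson r — exactly the coefficient of determination
of the simple linear regression between the two observers. Spearman rho is
Pearson on mid-ranks. A feature with zero variance in either observer has
undefined correlation and counts as non-reproducible. The CV uses the
population SD and the absolute mean (features such as cluster shade can be
negative); a zero mean flags the CV undefined. The relevancy test is the
classical pooled-variance Student t-test (the protocol says only "t-test");
observer-1 values feed the t-test, and both thresholds are strict
inequalities (p < 0.2, r > 0.8). Lowering the p threshold or raising the r
threshold can only remove features (tested monotonicity).

### SVM by SMO

The soft-margin dual with box constraint C = 1 is solved by sequential
minimal optimization with deterministic maximal-KKT-violation pair
selection and stopping tolerance 1e-3 on the violation gap; the bias is the
mean violation over free support vectors. The tests check the analytic
two-point solution exactly and 20 random problems against `kernlab::ipop`,
a generic convex-QP solver, to 1e-3 relative on the weights. Decision
values are invariant to affine rescaling of raw features because
standardization absorbs it (tested to 1e-6). Note that duplicating a
feature column does *not* leave decision values unchanged — the duplicate
halves the effective ridge penalty on that direction — but the optimum
splits the weight equally between copies and the predicted labels are
unchanged on separable data; the tests assert exactly that.

### Metric panel

Malignant is the positive class (the clinical motivation is not missing a
malignancy). Confidence intervals are unclipped Wald intervals
`p +/- 1.96 sqrt(p(1-p)/m)` with `m` the denominator of each rate; for the
confusion matrix TP = 10, FN = 0, TN = 9, FP = 1 the panel is sensitivity
100%, specificity 90% (71.4-108.6), PPV 90.9% (73.9-107.9), NPV 100%,
accuracy 95.0% (85.4-104.6) — intervals exceeding 100% are reported as-is,
which is the only convention consistent with intervals of this shape.
AUROC is the Mann-Whitney rank statistic with half credit for ties.

## The synthetic cohort

The generator emulates the study conditions: 40 benign and 41 malignant
subjects, 96 x 96 px images at 0.8 mm isotropic spacing (the study's mean
pixel size is about 0.8 mm). Benign lesions draw radii of 8-15 mm, are
nearly round (lobulation amplitude 0.08) and enhance uniformly with
Gaussian noise (SD 20 on a base of 400). Malignant lesions draw radii of
15-25 mm, are lobulated (amplitude 0.35, around 6 lobes), and add a smooth
heterogeneous enhancement field (SD 120) plus 3 bright anti-aliased
septa-like lines of width about 1.5 px through the lesion center region —
the size, shape and enhancement-heterogeneity contrasts the classifier is
supposed to exploit. A second observer mask displaces the boundary by a
smooth random radial field of SD 1.5 px; four vendors apply linear
intensity gains 1.0/1.15/0.9/1.05 and small offsets, assigned cyclically.
Masks are star-shaped radial constructions, hence always single connected
components; masks reaching within 2 px of the border are rejected. Each
subject owns an RNG stream derived from (cohort seed, subject index), so
cohorts are bit-identical across runs and stable under reordering.

None of these generator values is claimed by the source protocol, which
describes no quantitative lesion appearance; they are package choices made
once to give a clearly separable two-class population with realistic
within-class spread. What passing tests show is therefore that the
*pipeline machinery* is correct and that the method recovers a known
planted contrast; they say nothing about discrimination performance on real
patients, where class overlap, acquisition heterogeneity and segmentation
ambiguity are far larger. In the same spirit, the synthetic cohort's
reproducibility and CV percentages differ numerically from any real
cohort's; only structural properties (bands, orderings such as the
discretization-robust feature set having lower CV) are asserted.

## Problem sizes used by tests and the acceptance script

The package's own test conditions: the default cohort (40 + 41 subjects,
both observers, all 7 levels) for the end-to-end checks, with the holdout
AUROC summarized as a median over 20 cohort seeds; the CV study on 10
subjects per class, medians over 10 seeds; oracle equivalence on 200 random
8 x 8 images at L in {2, 4, 8}. `scripts/acceptance.R --seed N --out F`
re-runs the whole pipeline at one seed and writes the headline numbers
(feature counts, selected-feature count, reproducible fraction, CV-impacted
fraction, holdout metric panel, AUROC) as JSON.

## Known limitations

* 2D only: no 3D texture matrices, no volumetric shape descriptors.
* Offset-1 co-occurrence only; no multi-distance GLCM.
* The synthetic classes are deliberately well separated; holdout metrics
  near 100% are a property of the phantom population, not a clinical claim.
* PNG output is 8-bit (binary masks are exact); NIfTI is the lossless
  image format. DICOM is out of scope.
* The CV of a feature whose mean across levels approaches zero is
  unstable by definition (division by |mean|); such features are flagged
  rather than smoothed.
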