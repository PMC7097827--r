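---
title: "Quantifying aceto-whitening in paired cervicograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aceto-whitening in paired cervicograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervia)
```

## The measurement problem

Visual inspection with acetic acid (VIA) grades the cervix by how densely
the epithelium whitens after 3–5 % acetic acid: protein-rich high-grade
lesions (CIN2+) turn opaquely white, while normal and low-grade tissue
stays pink or whitens faintly. `cervia` turns that judgement into a
per-sector measurement on a *registered pair* of images. The unit of
analysis is the clock sector — one of 12 thirty-degree wedges about the
cervix center, because histopathology of the excised cervix is reported the
same way, giving each sector its own reference label. Grades map to the
screening dichotomy as NORMAL/CIN1 → VIA-negative and CIN2+ → VIA-positive:
only high-grade disease is treat-worthy, so low-grade whitening is
deliberately part of the negative class.

## Pipeline model and assumptions

**Specular removal.** Wet epithelium under a point light throws saturated
highlights. A pixel is specular when `max(R, G, B) >= f * 255` with
`f = 0.6` by default. The max over channels is used because a saturated
highlight saturates every channel, and a single bright channel (reddish
tissue) must not trigger removal; `f` applies to the fraction of the 8-bit
range, not to a luminance formula, which keeps the rule monotone in `f`
(lower threshold, superset mask). Masked pixels are replaced by a
1/distance-weighted average of unmasked pixels within a 5 px radius,
iterated so larger blobs fill inward from their rim; the method assumes
highlights are small relative to the anatomy they cover.

**ROI by bit-plane slicing.** The ectocervix is the reddest structure in
frame. Slicing the red channel into its 8 bit planes, the two most
significant planes (red ≥ 64 under the permissive OR reading; an AND option,
red ≥ 192, is exposed) capture it. Because raw bit-plane masks are speckled,
the mask is closed with a 5 px disc, reduced to its largest connected
component, and hole-filled. The pre and post masks are then intersected:
only tissue segmented in *both* phases is analyzed. The vaginal wall can
survive this when it abuts the cervix — a known residual, not corrected
further.

**Registration.** Three manual fiducials per image — cervix center and the
two cervical-os endpoints — define a rigid transform: rotate about the
center until the os line is horizontal (the `os_a` endpoint goes left;
a 180° flip enforces this, making orientation reproducible), then translate
the center to the canvas center. No scaling or deformation is applied, so
the method assumes the two exposures differ only by in-plane rotation and
translation. Images are resampled bilinearly, masks by nearest neighbor so
they stay binary; out-of-canvas pixels are excluded from the ROI.

**Clock convention.** Sector k is the half-open 30° arc centered on hour k,
hour 12 pointing up, hours increasing clockwise. Sector masks partition the
ROI pixel-exactly, and the assignment is equivariant: rotating a scene by
30° moves every pixel one hour forward. On real data the offset between the
pathologist's clock and the image clock would need a documented calibration;
the synthetic generator adopts this module's convention.

**The five predictors.** For each sector, with the pre/post pixel sets
restricted to the sector's mask:

- `d_ave`: per-pixel G/R and B/R ratios are histogrammed over [0, 2] in 256
  bins (ratios above 2 clip into the top bin; zero-red pixels are dropped;
  fewer than 50 valid pixels flags the feature missing). The feature is the
  signed shift of the histogram *mode index*, post minus pre, averaged over
  the two ratios. Modes are robust to tails, ratios cancel any common
  illumination factor, and ties break deterministically to the lowest bin.
  Aceto-whitening drives both ratios toward 1, so `d_ave` rises.
- `sd_green`, `sd_blue`: population standard deviations of the post-acetic
  green and blue channels — whitening broadens both histograms.
- `astar_mean`: mean CIELAB a\* of the post image (sRGB transfer, D65 white;
  the white point is a convention choice, and only differences matter).
  White patches mask the reddish stroma, lowering a\*.
- `glcm_correlation`: HSV saturation is computed for both phases; the
  difference `S_post − S_pre` on the sector's bounding box is quantized to
  8 levels over its own observed range, and one non-symmetric gray-level
  co-occurrence matrix per offset angle (0°, 45°, 90°, 135°, interpixel
  distance 5) is accumulated counting only pairs with both pixels inside
  the mask. The four matrices are summed *before* normalization, and the
  Haralick correlation of the pooled matrix is returned. Lesions change
  saturation coherently over tens of pixels, so their difference texture is
  spatially correlated; noise is not. A constant difference image has no
  defined correlation and flags the feature missing rather than imputing 0;
  rows with any missing feature are dropped from training with a message.

**Classifiers.** Features are z-scored with weighted means and weighted
(population) standard deviations learned from training rows only — weights
default to uniform; a sample-weight hook exists. Cross-validation refits
the standardization inside each fold by default (leak-free); a
`refit_per_fold = FALSE` flag reproduces the simpler fit-once protocol.
The three families use their field-standard implementations behind one
interface: `class::knn` (k = 5, Euclidean; score = positive-neighbor
fraction), `e1071::svm` with the polynomial kernel
`(1 + gamma x·y)^degree` (degree 4, cost 3, gamma 2.2; `coef0 = 1` matches
the parameterization those constants come from, and decision values are
mapped to (0, 1) by a monotone logistic link, which cannot change ranks or
AUC), and `rpart` with Gini splits grown fully then cost-complexity pruned
to the largest subtree within 20 total nodes — pruning rather than
best-first growth, with the node bound holding exactly. The summary
decision threshold is 0.5 on the positive-class score.

**Agreement statistics.** `roc_auc()` sweeps all thresholds and integrates
by trapezoid, which equals Mann–Whitney pair counting with ties at one
half. Cohen kappa uses the 2×2 closed form; its p-value is the asymptotic
normal test with the Fleiss null standard error — at n = 20 this reproduces
the magnitude of published reader-study p-values; an exact permutation
option was considered unnecessary at these sizes. Confusion matrices
reconstructed from printed rates round half away from zero and warn when a
printed rate is inconsistent with integer counts. A patient is called
positive if *any* of the 12 sectors is predicted positive — monotone by
construction and maximally sensitive, the right bias for screening.

## The synthetic generator

With no public cervicogram corpus, the generator renders what the features
assume, not what a camera sees. A scene is an ellipse of pinkish tissue
(red ≈ 120–135, green/blue ≈ 70–85) on a dark background, ringed by a
dimmer vaginal-wall annulus (red ≈ 52, below the bit-plane threshold so ROI
cleanup is non-trivially exercised), with a dark os slit whose endpoints
and midpoint are the fiducials, the whole scene drawn at a per-patient os
angle the registration must undo. Post-acetic abnormal sectors receive a
smooth multiplicative gain on green and blue (amplitude =
`whitening_strength`, default 0.5, spatially modulated by a low-frequency
field so the saturation-difference texture is correlated at the GLCM
working distance) plus additive speckle; CIN1 sectors get the same at 0.3×
strength, producing the confusable screen-negative class. Specular disks
are drawn at the 8-bit maximum and pixel noise (default SD 4) is added
independently per phase. The cervix base red is kept below the 60 %
specular threshold so that, in noise-free scenes, the specular detector
recovers exactly the rendered spots — one of the generator's testable
contracts.

Cohorts default to the study design: 20 patients, 60 % with at least one
CIN2+ sector (12 abnormal, 8 normal), a contiguous run of 2–5 abnormal
sectors per abnormal patient, per-patient seeds derived from one master
seed. What the generator does *not* emulate: vascular patterns (mosaicism,
punctation), out-of-plane pose changes, fluid and instrument artifacts,
camera response differences, or annotation error in the fiducials. Passing
tests therefore certify the pipeline's correctness and its sensitivity to
the modelled signal — not clinical performance, which on real images is far
from the near-perfect separation seen here.

## Numerical choices and degenerate inputs

- Coordinates are 1-based (row, col), origin top-left, R convention;
  fiducial JSON stores (x, y) = (col, row) pixels.
- Ratio histogram range [0, 2]: pink tissue sits below 1, whitening
  approaches 1; values above 2 are clipped rather than discarded.
- 8 GLCM levels over the slice's own range keeps small sectors' matrices
  populated; quantizing over a fixed global range would starve them.
- Bilinear warps sample the source boundary exactly (a position on the last
  row/col takes zero weight on the clamped far neighbor); positions outside
  the source are invalid and excluded from the ROI.
- An empty ROI flags all 12 slices invalid instead of erroring; empty and
  single-pixel slices flag their features missing.
- Degenerate kappa (marginals all in one class) returns `NA`, never 0.
- All randomness (scene content, cohort composition, holdout shuffle, fold
  assignment) flows from explicit integer seeds; reruns are bit-identical.

## Problem sizes used in the shipped checks

The test suite exercises single scenes at 192–256 px and full default runs
at 512 px with 20 patients; the feature-direction study uses 20 cohorts of
3 patients at 256 px, pooling roughly 700 sectors. These sizes were chosen
as the smallest at which every geometric property (sector partition,
Jaccard ≥ 0.95 ROI recovery, registration idempotence) is comfortably
non-marginal.

## Known limitations

- Rigid registration cannot compensate scale or out-of-plane changes
  between exposures; the generator never produces them.
- Bit-plane segmentation is a heuristic tied to red-dominant tissue; dark
  or blood-obscured cervices would defeat it.
- The os-slit sectors (3 and 9 o'clock after registration) carry extra
  channel variance from the slit itself; the classifiers absorb this, but
  the per-sector SD features are not pure whitening measures there.
- Patient-level aggregation has no notion of lesion size: one positive
  sector flips the patient.
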