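---
title: "Methods: texture-based macular edema detection in IR retinal images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture-based macular edema detection in IR retinal images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtexture)
```

## The problem and the approach

Macular edema (ME) — fluid accumulation at the macula — is normally graded
from OCT B-scans or flash fundus photography. Infrared
scanning-laser-ophthalmoscope (IR-SLO) reflectance images are acquired
without visible flashes, which patients tolerate better, but they are
low-contrast and noisy, and edema does not present as a crisply
segmentable lesion. The working hypothesis of this package is that edema
changes the *spatial texture* of the IR reflectance field: exudates,
microaneurysms and fluid pockets roughen what is otherwise a smooth,
spatially autocorrelated background. Texture statistics can therefore
separate ME eyes from controls without any lesion segmentation.

The pipeline has four stages:

1. **Pre-processing.** A median filter (edge-preserving salt/speckle
   removal), then contrast-limited adaptive histogram equalization (CLAHE)
   for uneven illumination. The optic disc — the brightest structure in
   the frame — is detected and excluded from all feature computation, so
   that its glare does not dominate the intensity statistics.
2. **Feature extraction.** Six first-order histogram moments and twenty
   gray-level co-occurrence matrix (GLCM) statistics per image, the latter
   computed in four adjacency directions (0°, 45°, 90°, 135°) at distance
   *d* and averaged.
3. **Feature selection.** A one-way ANOVA filter ranks features by their
   between-group F statistic; the top *k* (default 5) go to the
   classifier.
4. **Classification and diagnostics.** A linear SVM (default), KNN or
   Gaussian Naive Bayes under leave-one-out cross-validation (LOOCV) or a
   stratified 50/50 split; independently, each feature gets a diagnostic
   cut-off by Youden-index maximization on its ROC curve, with the
   trapezoidal AUC summarizing per-feature separability.

## The texture model

For a quantized image with gray levels $1..N_g$, the GLCM
$P_{\Delta}(i,j)$ is the probability that a pixel of level $i$ has a
neighbor of level $j$ at offset $\Delta$. With $p(i,j)$ the normalized
matrix, marginals $p_x, p_y$, sum/difference marginals $p_{x+y},
p_{x-y}$, and marginal moments $\mu_x, \mu_y, \sigma_x, \sigma_y$, the
workhorse features are

$$\text{contrast} = \sum_{i,j}(i-j)^2\,p(i,j), \qquad
\text{correlation} = \sum_{i,j}\frac{(i-\mu_x)(j-\mu_y)}{\sigma_x\sigma_y}\,p(i,j),$$

plus energy, entropy, homogeneity, dissimilarity, autocorrelation,
cluster shade/prominence, sum/difference averages, variances and
entropies, maximum probability, inverse difference (plain, normalized
`idn`, and moment-normalized `idmn`) and the two information measures of
correlation built from the joint and marginal entropies. GLCM correlation
is the feature of interest: a smooth reflectance field has strongly
similar neighboring pixels (correlation near 1), while lesion speckle and
a shorter background correlation length pull it down. The diagnostic
orientation is therefore "low correlation flags disease".

Assumptions worth making explicit: texture is treated as stationary over
the analyzed frame (the optic disc, the one structure that grossly
violates this, is masked out); the two groups are modeled as differing in
second-order spatial statistics, not in mean brightness (CLAHE largely
removes mean/illumination differences); and images are treated as
independent samples.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| `Ng` (gray levels) | 8 | levels | coarse quantization stabilizes co-occurrence estimates on ~65k-pixel frames; group means of level-indexed moments on 8 levels sit in the ranges typical for this application |
| `d` (pair distance) | 1 | px | nearest-neighbor co-occurrence, the classical default |
| `symmetric` | TRUE | — | each ordered pair counted both ways (Haralick's definition) |
| direction aggregation | mean over 0/45/90/135° | — | one rotation-tolerant value per feature; the unaveraged 4-direction block is also available |
| `median_kernel` | 3 | px | smallest edge-preserving window; removes single-pixel speckle |
| `clahe_clip` | 2 | × uniform bin height | community-standard clip limit |
| `clahe_tiles` | 8×8 | tiles | 32-px tiles at 256×256: local enough for illumination, large enough for stable histograms |
| `stretch_percentiles` | (2, 98) | % | robust range normalization before disc detection |
| `od_threshold_percentile` | 95 | % | the disc occupies ≈ 4% of a 256×256 frame, so the brightest 5% covers its plateau; a 99% threshold keeps too few pixels to cover the disc |
| `od_struct_radius` / `od_dilation` | 5 / 3 | px | disc-shaped structuring element wide enough to suppress 3-px vessels; final dilation adds a safety margin around the detected disc |
| selection `k` | 5 | features | matches the study protocol this pipeline re-implements |
| SVM `C` / KNN `k` / NB variance floor | 1 / 3 / 1e-9 | — | standard defaults; all configurable |

## What the synthetic generator emulates

Clinical IR-SLO datasets are rarely shareable, so the package ships a
seeded generator whose defaults *are* the study conditions the pipeline
is tested under: 23 cases and 18 controls (41 images) at 256×256, 8-bit.

Each image is composited as: a **Gaussian random field** background
(white noise smoothed at the group's correlation length — 8 px for
controls, 2 px for cases — then rescaled into the lower 5–75% of the
intensity range to leave headroom), dark **random-walk vessels** (6
tracks, width 3 px, contrast 50) each carrying a 1-px bright central
reflex streak, a bright **optic disc** (radius 30 px, plateau 240,
jittered ±20 px around a nasal anchor), case-only **lesion speckle** (30
Gaussian blobs, radius 2–6 px, amplitude 60) and additive Gaussian sensor
noise (sd 4). The Gaussian-field background was chosen because its single
smoothing scale maps monotonically onto GLCM correlation — the pipeline's
discriminative feature — so ground-truth effect direction and approximate
strength are controllable with one knob. A `null_cohort` switch renders
both groups under the control parameters with no lesions anywhere, for
type-I-error studies.

Each image is rendered under its own RNG substream keyed by (seed,
index), so a cohort is a pure function of its spec and any subset is
reproducible.

What the generator does **not** emulate: real fundus anatomy (macula,
nerve-fiber striations), the IR-SLO optical transfer function, spatially
varying illumination beyond what CLAHE sees, graded disease severity, and
the within-subject correlation of two-eye contributions (every image is
independent; a clinical cohort with both eyes of some subjects violates
this). Passing tests on the synthetic twin therefore demonstrate that the
*machinery* — features, ranking, cut-offs, validation — behaves correctly
and recovers a known texture effect of realistic direction and size; they
do not certify clinical accuracy on real IR images, where effect sizes
are unknown and confounds (pupil size, media opacity, focus) exist.

## Numerical choices

- All entropies use the natural logarithm with $0\log 0 := 0$; zero terms
  are skipped exactly, never epsilon-padded.
- Gray levels are indexed $1..N_g$ in every formula, fixing the scale of
  autocorrelation, sum average and the cluster moments. Quantization uses
  uniform bins over the in-mask min–max; the maximum maps to $N_g$.
- Cluster shade uses the cubic and cluster prominence the quartic
  exponent (the standard convention). Sum variance is centered on the sum
  average by default; `sum_variance_center = "sum_entropy"` restores the
  older centering.
- Undefined features (correlation when a marginal is degenerate, IMC1
  when both marginal entropies vanish, histogram skewness/kurtosis at
  zero variance) are `NA`, excluded from ranking, and never imputed.
- ROC thresholds sit at midpoints between consecutive unique scores (plus
  ±∞), so reported cut-offs fall between observed values. Both
  orientations ("positive if >" and "positive if ≤") are evaluated; the
  AUC is reported for the orientation with AUC ≥ 0.5, and the Youden
  search maximizes J over *every* threshold/orientation pair, breaking
  ties toward higher sensitivity (screening preference), then lower
  threshold. Identical scores give a degenerate ROC with AUC 0.5.
- The trapezoidal AUC is, by construction, the tie-corrected Mann–Whitney
  U divided by $n_1 n_2$; the test suite asserts this identity to 1e-12
  and cross-checks against pROC.
- Features are z-scored with training-fold statistics inside every
  validation fold (constant features pass through unscaled); a
  single-class LOOCV training fold predicts its remaining class.
- Median filtering reflects at borders; the filter never invents values
  absent from the neighborhood. CLAHE grids of fewer than 4 tiles fall
  back to global clipped equalization (tile interpolation is meaningless
  there); a constant image is its own equalization.
- Optic-disc detection thresholds strictly above the brightness
  percentile, keeps the largest connected component, and returns an empty
  mask (with a warning) when nothing survives — a flat image has no disc.

## Open design decisions

- **Selection protocol.** The re-implemented protocol ranks features on
  the full dataset before LOOCV (`nested = FALSE`, the default). With 41
  samples this is optimistically biased; `nested = TRUE` refits the
  ranking inside every training fold and is the recommended setting for
  new studies. The package's own null-cohort permutation test uses the
  nested protocol precisely because the non-nested one is biased by
  construction on permuted labels.
- **Validation scheme.** Both LOOCV (default) and a stratified seeded
  50/50 split are provided; the source protocol describes both without
  reconciling them.
- **Enhancement order.** Median filter then CLAHE by default; the
  `order` config entry permits the reverse.
- **Masked features.** Features are computed on the disc-masked frame by
  default (`mask_od = FALSE` disables), since disc glare otherwise leaks
  into every intensity statistic.

## Problem sizes used by the test suite

The statistical tests run at sizes chosen to make their assertions sharp
yet cheap: oracle equivalence on 100 random masked 12×12 images × 4
directions; AUC/Youden identities on 1,000 random score sets; type-I
error on 100 null cohorts of 8+8 images at 64×64 (Bonferroni-adjusted
minimum p > 0.05 expected in ≥ 90% of cohorts); a 50-permutation LOOCV
null on one 20+20 cohort at 64×64 (mean accuracy expected in 40–60%);
monotonicity of GLCM correlation across 5 smoothing scales × 10
backgrounds at 128×128 (Spearman ρ > 0.9); and the full default 41-image
cohort at 256×256 for the end-to-end classification and best-feature
checks.

## Known limitations

- The synthetic effect (correlation length 8 vs 2 px plus lesions) is
  deliberately strong; the perfect LOOCV separation it yields says the
  pipeline implements its protocol faithfully, not that real IR cohorts
  separate perfectly.
- GLCM features depend on $N_g$, $d$ and the quantization rule; values
  are comparable only within one configuration.
- The optic-disc detector assumes one dominant bright blob; it will grab
  the brighter of two candidate regions and can fail (empty mask) on
  frames whose brightest 5% is saturated background rather than disc.
- No probability calibration, AUC confidence intervals, multi-class
  support, or vessel segmentation.
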