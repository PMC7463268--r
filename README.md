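# irtexture

Texture-based detection of macular edema (ME) in flashless infrared
retinal images.

## The problem

Macular edema — fluid swelling at the center of the retina — is usually
assessed with OCT or flash fundus photography. Infrared
scanning-laser-ophthalmoscope (IR-SLO) images are acquired without
visible flashes and are routinely collected alongside OCT, but they are
noisy, low-contrast, and edema has no crisp boundary in them. `irtexture`
implements a screening pipeline built on a different observation: edema
*roughens the spatial texture* of the IR reflectance field. The package
is aimed at researchers in retinal image analysis who want a tested,
reproducible reference implementation of this texture protocol, together
with a synthetic cohort generator for validating every stage against
known ground truth.

## The method

For each image the pipeline computes, after median filtering, CLAHE
contrast enhancement and optic-disc masking:

- **First-order histogram moments** of the `Ng`-level quantized
  intensities: mean, variance, skewness, kurtosis, energy
  `Σ p(i)²`, entropy `−Σ p(i) ln p(i)`.
- **GLCM (Haralick) features.** With `p(i,j)` the normalized gray-level
  co-occurrence matrix at distance `d = 1` in direction θ, and marginal
  moments `μx, μy, σx, σy`:

  ```
  contrast     = Σᵢⱼ (i−j)² p(i,j)
  correlation  = Σᵢⱼ (i−μx)(j−μy) p(i,j) / (σx σy)
  homogeneity  = Σᵢⱼ p(i,j) / (1 + (i−j)²)
  ```

  plus energy, entropy, dissimilarity, autocorrelation, cluster
  shade/prominence, sum/difference average/variance/entropy, maximum
  probability, inverse difference (plain / normalized / moment-
  normalized) and the information measures of correlation IMC1 and IMC2 —
  twenty statistics, each averaged over the four adjacency directions
  0°, 45°, 90°, 135°.

Features are then ranked by a one-way ANOVA F statistic between cases
and controls; the top 5 feed a linear SVM evaluated with leave-one-out
cross-validation (KNN, Gaussian Naive Bayes and a stratified 50/50 split
are also available). Independently, every feature receives a diagnostic
cut-off by maximizing the Youden index `J = sensitivity + specificity − 1`
over its ROC curve; the trapezoidal AUC (equal to the tie-corrected
Mann–Whitney statistic) summarizes per-feature separability. A smooth
healthy background has GLCM correlation near 1, so *low* correlation
flags disease.

Because clinical IR-SLO images are rarely shareable, the package includes
a seeded generator of IR-like cohorts (Gaussian-random-field background
whose correlation length differs between groups, dark vessels with a
bright central reflex, a bright optic disc, case-only lesion speckle) so
the whole pipeline can be exercised end-to-end against known truth.

## Worked example

Run the default study twin — 41 synthetic images (23 ME cases, 18
controls, 256×256) with a strong injected texture difference — through
the full pipeline:

```r
library(irtexture)
res <- run_pipeline(run_config())

print(res$report)
#> <classifier_report> svm_linear / loocv: sens 100.0%, spec 100.0%, acc 100.0% (TP 23 FP 0 TN 18 FN 0)

head(res$diagnostics[, c("feature", "cutoff", "orientation",
                         "sensitivity", "specificity", "auc")], 5)
#>              feature     cutoff orientation sensitivity specificity auc
#> 1           contrast 0.47979073           >         100         100   1
#> 2        correlation 0.88559052          <=         100         100   1
#> 3 difference_entropy 0.71864002           >         100         100   1
#> 4      dissimilarity 0.35113027           >         100         100   1
#> 5             energy 0.09790835          <=         100         100   1

cm <- res$comparison
cm[cm$feature %in% c("contrast", "correlation", "homogeneity"), ]
#>        feature mean_control mean_case      F         p
#> 8     contrast       0.3471    0.6364  489.1 1.128e-23
#> 9  correlation       0.9251    0.8515  510.8 5.129e-24
#> 13 homogeneity       0.8938    0.7790 2978.2 1.905e-38
```

Reading the output: the LOOCV linear SVM on the five top-ranked ANOVA
features classifies every image correctly (sensitivity = specificity =
accuracy = 100%). The per-feature diagnostics table is sorted by AUC;
GLCM correlation reaches a perfect AUC of 1.0 with the cut-off rule
"ME if correlation ≤ 0.886" — controls average 0.925, cases 0.852,
matching the injected effect direction (cases are generated with a
shorter background correlation length plus lesion speckle). On this
strongly separable synthetic cohort several texture features reach
AUC 1.0 simultaneously.

Artifacts (`features.csv`, `ranking.csv`, `diagnostics.csv`,
`report.json`, resolved config, log) are written when `output_dir` is
given; `run_pipeline(cfg, output_dir = "out/")`. Real image directories
are analyzed with
`run_config(input = list(mode = "directory", dir = "images/"))`, where
the directory holds single-channel PNG/TIFF files and a `labels.csv`
with columns `image_id,label` (`case` / `control`). A thin CLI wrapper
for simulate / run-all / validate lives in
`inst/scripts/irtexture-pipeline.R`.

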