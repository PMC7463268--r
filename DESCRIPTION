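Package: irtexture
Title: Texture-Based Detection of Macular Edema in Infrared Retinal Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for flashless, texture-based screening of
    macular edema in infrared scanning-laser-ophthalmoscope (IR-SLO) retinal
    images. Images are denoised (median filter), contrast-enhanced (CLAHE) and
    optic-disc masked; first-order histogram moments and gray-level
    co-occurrence matrix (GLCM) Haralick features are extracted over four
    adjacency directions; features are ranked by one-way ANOVA; per-feature
    diagnostic cut-offs are derived from ROC curves via the Youden index; and
    case/control status is classified with linear SVM, KNN or Gaussian Naive
    Bayes under leave-one-out or split-half validation. A seeded synthetic
    cohort generator produces labeled IR-like images whose two classes differ
    in spatial autocorrelation, for end-to-end testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    stats,
    utils,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
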