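make_hist <- function(p) {
  structure(list(counts = p * 100, probabilities = p, Ng = length(p)),
            class = "intensity_histogram")
}

test_that("histogram moments evaluate the stated formulas", {
  one <- histogram_features(make_hist(c(0, 0, 1)))
  expect_equal(unname(one[c("hist_mean", "hist_variance",
                            "hist_energy", "hist_entropy")]),
               c(3, 0, 1, 0))
  expect_true(all(is.na(one[c("hist_skewness", "hist_kurtosis")])))
  two <- histogram_features(make_hist(c(0.5, 0.5)))
  expect_equal(unname(two), c(1.5, 0.25, 0, 1, 0.5, log(2)),
               tolerance = 1e-12)
  sym <- histogram_features(make_hist(c(0.2, 0.3, 0.3, 0.2)))
  expect_equal(unname(sym["hist_skewness"]), 0, tolerance = 1e-12)
})

test_that("degenerate co-occurrence matrices give the hand-worked features", {
  diag1 <- make_qimg(matrix(3L, 4, 4), 8)
  f <- haralick_features(compute_glcm(diag1, 0, 1))
  expect_equal(unname(f[c("contrast", "dissimilarity", "homogeneity",
                          "energy", "entropy", "maximum_probability",
                          "idn", "idmn")]),
               c(0, 0, 1, 1, 0, 1, 1, 1), tolerance = 1e-12)
  expect_true(is.na(f["correlation"]))
})

test_that("the checkerboard GLCM gives the hand-worked features", {
  checker <- make_qimg(matrix(rep(c(1L, 2L), 8), 4, 4), 2)
  g <- compute_glcm(checker, 90, 1)   # vertical neighbors alternate
  expect_equal(g$P, matrix(c(0, 0.5, 0.5, 0), 2))
  f <- haralick_features(g)
  expect_equal(unname(f["contrast"]), 1, tolerance = 1e-12)
  expect_equal(unname(f["dissimilarity"]), 1, tolerance = 1e-12)
  expect_equal(unname(f["homogeneity"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(f["energy"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(f["entropy"]), log(2), tolerance = 1e-12)
  expect_equal(unname(f["correlation"]), -1, tolerance = 1e-12)
  expect_equal(unname(f["sum_average"]), 3, tolerance = 1e-12)
  expect_equal(unname(f["sum_variance"]), 0, tolerance = 1e-12)
  expect_equal(unname(f["maximum_probability"]), 0.5, tolerance = 1e-12)
})

test_that("features match an independently coded literal-formula oracle", {
  set.seed(22)
  for (rep in 1:25) {
    Ng <- sample(3:8, 1)
    lv <- matrix(sample.int(Ng, 100, TRUE), 10, 10)
    g <- compute_glcm(make_qimg(lv, Ng), sample(c(0, 45, 90, 135), 1), 1)
    got <- haralick_features(g)
    want <- oracle_haralick(g$P)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("feature bounds hold on random images", {
  set.seed(23)
  for (rep in 1:10) {
    img <- gray_image(matrix(sample(0:255, 400, TRUE), 20), 8)
    q <- quantize(img, Ng = 8)
    f <- haralick_features(compute_glcm(q, 45, 1))
    expect_true(all(f[c("energy", "homogeneity", "maximum_probability",
                        "idn", "idmn")] > 0))
    expect_true(all(f[c("energy", "homogeneity", "maximum_probability",
                        "idn", "idmn")] <= 1))
    expect_true(abs(f["correlation"]) <= 1 + 1e-12)
    expect_true(f["imc2"] >= 0 && f["imc2"] < 1)
    expect_true(all(f[c("entropy", "sum_entropy", "difference_entropy")] >=
                      0))
    expect_true(f["entropy"] <= 2 * log(8) + 1e-12)
  }
})

test_that("sum variance centering is switchable", {
  set.seed(24)
  lv <- matrix(sample.int(6, 100, TRUE), 10, 10)
  g <- compute_glcm(make_qimg(lv, 6), 0, 1)
  sa <- haralick_features(g, sum_variance_center = "sum_average")
  se <- haralick_features(g, sum_variance_center = "sum_entropy")
  k <- 2:(2 * g$Ng)
  sent <- -sum(ifelse(g$p_xplusy > 0,
                      g$p_xplusy * log(g$p_xplusy), 0))
  expect_equal(unname(se["sum_variance"]),
               sum((k - sent)^2 * g$p_xplusy), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sa["sum_variance"], se["sum_variance"])))
})

test_that("an all-true mask is the same as no mask", {
  set.seed(25)
  img <- gray_image(matrix(sample(0:255, 1024, TRUE), 32), 8)
  a <- extract_features(img, mask = NULL)
  b <- extract_features(img, mask = matrix(TRUE, 32, 32))
  expect_identical(a, b)
})

test_that("rotating the image by 90 degrees permutes directions only", {
  set.seed(26)
  img <- gray_image(matrix(sample(0:255, 1024, TRUE), 32), 8)
  rot <- gray_image(t(unclass(img))[32:1, ], 8)   # 90-degree rotation
  a <- extract_features(img)
  b <- extract_features(rot)
  pa <- attr(a, "per_direction"); pb <- attr(b, "per_direction")
  expect_equal(pa["dir_0", ], pb["dir_90", ], tolerance = 1e-9)
  expect_equal(pa["dir_90", ], pb["dir_0", ], tolerance = 1e-9)
  expect_equal(pa["dir_45", ], pb["dir_135", ], tolerance = 1e-9)
  expect_equal(as.vector(a), as.vector(b), tolerance = 1e-9)
})

test_that("direction-averaged correlation separates noise from smooth fields", {
  set.seed(27)
  rough <- make_background(cohort_spec(height = 128, width = 128,
                                       corr_length_control = 0.01,
                                       seed = 1), "control")
  smooth <- make_background(cohort_spec(height = 128, width = 128,
                                        corr_length_control = 8,
                                        seed = 1), "control")
  fr <- extract_features(rough)
  fs <- extract_features(smooth)
  expect_lt(abs(fr["correlation"]), 0.1)
  expect_gt(fs["correlation"], 0.5)
})

test_that("feature tables carry ids, labels and deterministic columns", {
  coh <- generate_cohort(test_spec(n_cases = 2, n_controls = 2, seed = 10))
  tab <- extract_feature_table(coh)
  expect_equal(nrow(tab), 4L)
  expect_equal(names(tab)[1:2], c("image_id", "label"))
  expect_true(all(c("hist_mean", "correlation", "idmn") %in% names(tab)))
  tab2 <- extract_feature_table(coh)
  expect_identical(tab, tab2)
  # direction-resolved columns appear on request
  tabd <- extract_feature_table(coh, per_direction = TRUE)
  expect_true(all(c("correlation_0", "correlation_45", "correlation_90",
                    "correlation_135") %in% names(tabd)))
  expect_equal(rowMeans(tabd[, paste0("contrast_", c(0, 45, 90, 135))]),
               tabd$contrast, tolerance = 1e-12, ignore_attr = TRUE)
})
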