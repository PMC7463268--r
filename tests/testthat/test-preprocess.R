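test_that("median filter matches the brute-force neighborhood oracle", {
  set.seed(14)
  img <- gray_image(matrix(sample(0:255, 256, TRUE), 16), 8)
  for (k in c(3L, 5L)) {
    expect_equal(unclass(median_filter(img, k)),
                 oracle_median_filter(unclass(img), k),
                 ignore_attr = TRUE)
  }
})

test_that("median filter handles degenerate and outlier inputs", {
  const <- gray_image(matrix(40, 8, 8), 8)
  expect_identical(unclass(median_filter(const, 3)), unclass(const))
  salt <- matrix(40, 8, 8); salt[4, 5] <- 255
  restored <- median_filter(gray_image(salt, 8), 3)
  expect_equal(unclass(restored)[4, 5], 40)
  expect_true(all(unclass(restored) == 40))
  # medians never invent values absent from the input
  set.seed(15)
  sparse <- gray_image(matrix(sample(c(10, 60, 200), 64, TRUE), 8), 8)
  expect_true(all(unclass(median_filter(sparse, 3)) %in% c(10, 60, 200)))
  expect_error(median_filter(const, 2), "odd")
  expect_error(median_filter(const, 9), "exceeds")
})

test_that("CLAHE respects range, degeneracy and the global-equalization limit", {
  const <- gray_image(matrix(99, 32, 32), 8)
  expect_identical(unclass(ir_clahe(const)), unclass(const))
  set.seed(16)
  img <- gray_image(matrix(sample(20:180, 64 * 64, TRUE), 64), 8)
  out <- ir_clahe(img)
  expect_true(all(unclass(out) >= 0 & unclass(out) <= 255))
  # one tile with an unbounded clip limit is plain global equalization
  eq <- ir_clahe(img, clip = 1e9, tiles = c(1, 1))
  v <- as.vector(unclass(img))
  oracle <- round(stats::ecdf(v)(v) * 255)
  expect_equal(as.vector(unclass(eq)), oracle)
  expect_error(ir_clahe(gray_image(matrix(1:32, 4), 8), tiles = c(8, 8)),
               "smaller")
})

test_that("contrast stretch applies the stated linear map", {
  img <- gray_image(matrix(c(10, 20, 30, 40), 2), 8)
  expect_equal(sort(as.vector(unclass(contrast_stretch(img, 0, 100)))),
               c(0, 85, 170, 255))
  full <- gray_image(matrix(c(0, 100, 200, 255), 2), 8)
  expect_identical(unclass(contrast_stretch(full, 0, 100)), unclass(full))
  const <- gray_image(matrix(7, 2, 2), 8)
  expect_warning(out <- contrast_stretch(const), "degenerate")
  expect_identical(unclass(out), unclass(const))
  expect_error(contrast_stretch(img, 50, 10), "low_pct")
})

test_that("optic disc segmentation recovers known geometry", {
  coh <- generate_cohort(cohort_spec(n_cases = 0, n_controls = 1, seed = 3))
  rec <- coh[[1]]
  mask <- segment_optic_disc(rec$image)
  d <- sqrt(outer((seq_len(256) - rec$truth$disc_center[1])^2,
                  (seq_len(256) - rec$truth$disc_center[2])^2, `+`))
  truth <- d <= rec$truth$disc_radius
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.7)
})

test_that("optic disc segmentation handles flat and two-disc images", {
  flat <- gray_image(matrix(70, 128, 128), 8)
  expect_warning(m <- segment_optic_disc(flat), "empty mask")
  expect_false(any(m))
  # two bright discs: only the larger is kept
  base <- gray_image(matrix(80, 128, 128), 8)
  two <- add_optic_disc(add_optic_disc(base, c(40, 40), 18, 255),
                        c(100, 100), 8, 255)
  m2 <- segment_optic_disc(two)
  expect_true(m2[40, 40])
  expect_false(m2[100, 100])
})

test_that("preprocess returns an enhanced image and a consistent mask", {
  coh <- generate_cohort(cohort_spec(n_cases = 1, n_controls = 0, seed = 8))
  rec <- coh[[1]]
  cfg_off <- preprocess_config(mask_od = FALSE)
  out_off <- preprocess(rec$image, cfg_off)
  expect_true(all(out_off$mask))
  out <- preprocess(rec$image)
  out2 <- preprocess(rec$image)
  expect_identical(unclass(out$image), unclass(out2$image))
  expect_identical(out$mask, out2$mask)
  # the enhancement is the same with or without masking
  expect_identical(unclass(out$image), unclass(out_off$image))
  # masked-out fraction is within a factor 2 of the true disc area
  disc_frac <- pi * rec$truth$disc_radius^2 / (256 * 256)
  masked_frac <- mean(!out$mask)
  expect_gt(masked_frac, disc_frac / 2)
  expect_lt(masked_frac, disc_frac * 2)
  # >= 90% of true disc pixels are excluded from analysis
  d <- sqrt(outer((seq_len(256) - rec$truth$disc_center[1])^2,
                  (seq_len(256) - rec$truth$disc_center[2])^2, `+`))
  truth <- d <= rec$truth$disc_radius
  expect_gte(sum(truth & !out$mask) / sum(truth), 0.9)
})

test_that("preprocess_config validates its parameters", {
  expect_error(preprocess_config(median_kernel = 4), "odd")
  expect_error(preprocess_config(clahe_clip = 0), "clip")
  expect_error(preprocess_config(stretch_percentiles = c(98, 2)),
               "stretch_percentiles")
  expect_error(preprocess_config(order = c("median", "sharpen")), "order")
})
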