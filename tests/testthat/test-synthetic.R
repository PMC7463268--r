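test_that("cohort generation is deterministic and correctly labeled", {
  spec <- test_spec(n_cases = 3, n_controls = 2, seed = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_equal(length(a), 5L)
  expect_equal(sum(vapply(a, `[[`, "", "label") == "case"), 3L)
  for (i in seq_along(a)) {
    expect_identical(unclass(a[[i]]$image), unclass(b[[i]]$image))
    expect_identical(a[[i]]$truth, b[[i]]$truth)
  }
  # per-image substreams: the same record is reproducible from a smaller run
  small <- generate_cohort(test_spec(n_cases = 1, n_controls = 0, seed = 5))
  expect_identical(unclass(small[[1]]$image), unclass(a[[1]]$image))
})

test_that("spec invariants are enforced", {
  expect_error(cohort_spec(n_cases = 0, n_controls = 0), "at least one")
  expect_error(cohort_spec(corr_length_case = 0), "correlation lengths")
  expect_error(cohort_spec(height = 16), ">= 32")
  expect_error(cohort_spec(lesion_radius_range = c(5, 2)), "inverted")
})

test_that("unsmoothed background behaves as i.i.d. noise", {
  spec <- cohort_spec(n_cases = 1, n_controls = 1, height = 256,
                      width = 256, corr_length_control = 0.01,
                      corr_length_case = 0.01, seed = 2)
  set.seed(2)
  img <- make_background(spec, "control")
  q <- quantize(img, Ng = 8)
  for (ang in c(0, 45, 90, 135)) {
    corr <- haralick_features(compute_glcm(q, ang))["correlation"]
    expect_lt(abs(corr), 0.1)
  }
})

test_that("same seed and group give identical backgrounds", {
  spec <- test_spec(seed = 9)
  set.seed(31); a <- make_background(spec, "case")
  set.seed(31); b <- make_background(spec, "case")
  expect_identical(unclass(a), unclass(b))
})

test_that("longer correlation length raises mean GLCM correlation", {
  spec <- cohort_spec(n_cases = 20, n_controls = 20, height = 128,
                      width = 128, corr_length_control = 8,
                      corr_length_case = 2, seed = 4)
  ctrl <- sapply(1:20, function(i)
    background_correlation(spec, "control", 1000 + i))
  case <- sapply(1:20, function(i)
    background_correlation(spec, "case", 2000 + i))
  expect_gt(mean(ctrl), mean(case))
  # effect-direction property at alpha = 0.01, one-sided
  expect_lt(t.test(ctrl, case, alternative = "greater")$p.value, 0.01)
})

test_that("optic disc compositing follows its geometry", {
  base <- gray_image(matrix(100, 64, 64), 8)
  # zero contrast: brightness equal to the background level
  same <- add_optic_disc(base, c(32, 32), 10, 100)
  expect_identical(unclass(same), unclass(base))
  # bright disc raises the inside mean above the outside
  disc <- add_optic_disc(base, c(32, 32), 12, 255)
  d <- sqrt(outer((1:64 - 32)^2, (1:64 - 32)^2, `+`))
  expect_gt(mean(unclass(disc)[d <= 12]), mean(unclass(disc)[d > 12]))
  # partially off-border: raised pixels are exactly disc-intersect-frame
  part <- add_optic_disc(base, c(2, 2), 10, 255)
  changed <- unclass(part) != unclass(base)
  d2 <- sqrt(outer((1:64 - 2)^2, (1:64 - 2)^2, `+`))
  expect_identical(changed, d2 < 10)  # falloff reaches zero at the rim
  expect_error(add_optic_disc(base, c(-50, -50), 10, 255), "outside")
})

test_that("vessel compositing honors degenerate parameters", {
  spec <- test_spec(vessel_count = 0)
  base <- gray_image(matrix(120, 64, 64), 8)
  expect_identical(unclass(add_vessels(base, spec)), unclass(base))
  spec2 <- test_spec(vessel_count = 3, vessel_contrast = 0)
  set.seed(8)
  expect_identical(unclass(add_vessels(base, spec2)), unclass(base))
})

test_that("vessels add co-occurrence contrast", {
  spec <- test_spec(height = 128, width = 128, vessel_count = 2,
                    vessel_width = 3, vessel_contrast = 80)
  set.seed(12)
  smooth <- make_background(cohort_spec(height = 128, width = 128,
                                        corr_length_control = 8, seed = 1),
                            "control")
  set.seed(13)
  vessel <- add_vessels(smooth, spec)
  con <- function(img) {
    q <- quantize(img, Ng = 8)
    mean(sapply(c(0, 45, 90, 135), function(a)
      haralick_features(compute_glcm(q, a))["contrast"]))
  }
  expect_gt(con(vessel), con(smooth))
})

test_that("lesion compositing is identity-safe and records truth", {
  base <- gray_image(matrix(90, 64, 64), 8)
  strip <- function(img) {
    attr(img, "lesions") <- NULL
    unclass(img)
  }
  none <- add_lesions(base, test_spec(lesion_count = 0))
  expect_identical(strip(none), unclass(base))
  expect_equal(nrow(attr(none, "lesions")), 0L)
  flat <- add_lesions(base, test_spec(lesion_amplitude = 0))
  expect_identical(strip(flat), unclass(base))
  set.seed(21)
  spotted <- add_lesions(base, test_spec(lesion_count = 12))
  tr <- attr(spotted, "lesions")
  expect_equal(nrow(tr), 12L)
  expect_true(all(tr$row >= 1 & tr$row <= 64 & tr$col >= 1 & tr$col <= 64))
})

test_that("lesion speckle lowers GLCM correlation of a smooth field", {
  set.seed(33)
  smooth <- make_background(cohort_spec(height = 128, width = 128,
                                        corr_length_control = 8, seed = 1),
                            "control")
  set.seed(34)
  spotted <- add_lesions(smooth, test_spec(lesion_count = 30,
                                           lesion_amplitude = 80))
  corr <- function(img) {
    q <- quantize(img, Ng = 8)
    mean(sapply(c(0, 45, 90, 135), function(a)
      haralick_features(compute_glcm(q, a))["correlation"]))
  }
  expect_lt(corr(spotted), corr(smooth))
})

test_that("all compositing stages stay inside the intensity range", {
  for (seed in 1:3) {
    coh <- generate_cohort(test_spec(n_cases = 1, n_controls = 1,
                                     seed = seed,
                                     lesion_amplitude = 150,
                                     vessel_contrast = 120))
    for (rec in coh) {
      expect_true(all(unclass(rec$image) >= 0 &
                        unclass(rec$image) <= 255))
      expect_true(all(rec$truth$disc_center >= 1 &
                        rec$truth$disc_center <= 64))
    }
  }
})

test_that("cohorts round-trip through disk with labels and truth", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(test_spec(n_cases = 2, n_controls = 1, seed = 6))
  write_cohort(coh, dir)
  labs <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(labs), 3L)
  expect_setequal(labs$label, c("case", "control"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_setequal(names(truth), labs$image_id)
  back <- read_gray_image(file.path(dir, paste0(coh[[1]]$image_id, ".png")))
  expect_equal(unclass(back), unclass(coh[[1]]$image),
               ignore_attr = TRUE)
})
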