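#' First-order histogram features
#'
#' Central moments of the quantized intensity histogram, with levels
#' `i = 1..Ng` as the abscissa: mean, variance, skewness, kurtosis
#' (non-excess), energy (sum of squared probabilities) and Shannon entropy
#' (natural log, `0 log 0 := 0`). Skewness and kurtosis are undefined
#' (returned as `NA`) when the variance is zero.
#'
#' @param hist an [glcm_histogram()] result.
#' @return Named numeric vector `hist_mean`, `hist_variance`,
#'   `hist_skewness`, `hist_kurtosis`, `hist_energy`, `hist_entropy`;
#'   undefined entries are `NA`.
#' @export
histogram_features <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  p <- hist$probabilities
  i <- seq_along(p)
  m <- sum(i * p)
  v <- sum((i - m)^2 * p)
  s <- sqrt(v)
  c(hist_mean = m,
    hist_variance = v,
    hist_skewness = if (s > 0) sum((i - m)^3 * p) / s^3 else NA_real_,
    hist_kurtosis = if (s > 0) sum((i - m)^4 * p) / s^4 else NA_real_,
    hist_energy = sum(p^2),
    hist_entropy = -sum(xlogx(p)))
}

#' Haralick features of one GLCM
#'
#' Evaluates the texture statistics of a single co-occurrence matrix with
#' gray levels indexed `1..Ng`. All entropies use the natural logarithm with
#' `0 log 0 := 0` (zero-probability terms are skipped exactly; no epsilon
#' offsets). Cluster shade uses the cubic and cluster prominence the quartic
#' exponent (the standard convention). `correlation` is undefined (`NA`)
#' when either marginal standard deviation is zero; `imc1` is undefined when
#' `max(HX, HY) = 0`.
#'
#' @param glcm a [compute_glcm()] result.
#' @param sum_variance_center `"sum_average"` (default) centers the sum
#'   variance on the sum average; `"sum_entropy"` uses Haralick's original
#'   centering on the sum entropy.
#' @return Named numeric vector of 20 features: `autocorrelation`,
#'   `contrast`, `correlation`, `cluster_shade`, `cluster_prominence`,
#'   `dissimilarity`, `homogeneity`, `difference_variance`,
#'   `difference_entropy`, `entropy`, `energy`, `sum_average`,
#'   `sum_entropy`, `sum_variance`, `maximum_probability`,
#'   `inverse_difference`, `imc1`, `imc2`, `idn`, `idmn`.
#' @export
haralick_features <- function(glcm,
                              sum_variance_center = c("sum_average",
                                                      "sum_entropy")) {
  stopifnot(inherits(glcm, "glcm"))
  sum_variance_center <- match.arg(sum_variance_center)
  P <- glcm$P; Ng <- glcm$Ng
  i <- seq_len(Ng)
  ii <- matrix(i, Ng, Ng); jj <- t(ii)

  k_sum <- 2:(2 * Ng)            # index of p_xplusy
  k_diff <- 0:(Ng - 1L)          # index of p_xminusy
  psum <- glcm$p_xplusy; pdiff <- glcm$p_xminusy

  sa <- sum(k_sum * psum)
  se <- -sum(xlogx(psum))
  sv_center <- if (sum_variance_center == "sum_average") sa else se
  mu_diff <- sum(k_diff * pdiff)

  corr <- if (glcm$sigma_x > 0 && glcm$sigma_y > 0) {
    sum(((ii - glcm$mu_x) / glcm$sigma_x) *
          ((jj - glcm$mu_y) / glcm$sigma_y) * P)
  } else NA_real_
  denom <- max(glcm$HX, glcm$HY)
  imc1 <- if (denom > 0) (glcm$HXY - glcm$HXY1) / denom else NA_real_
  imc2 <- sqrt(max(0, 1 - exp(-2 * (glcm$HXY2 - glcm$HXY))))

  c(autocorrelation = sum(ii * jj * P),
    contrast = sum((ii - jj)^2 * P),
    correlation = corr,
    cluster_shade = sum((ii + jj - glcm$mu_x - glcm$mu_y)^3 * P),
    cluster_prominence = sum((ii + jj - glcm$mu_x - glcm$mu_y)^4 * P),
    dissimilarity = sum(abs(ii - jj) * P),
    homogeneity = sum(P / (1 + (ii - jj)^2)),
    difference_variance = sum((k_diff - mu_diff)^2 * pdiff),
    difference_entropy = -sum(xlogx(pdiff)),
    entropy = glcm$HXY,
    energy = sum(P^2),
    sum_average = sa,
    sum_entropy = se,
    sum_variance = sum((k_sum - sv_center)^2 * psum),
    maximum_probability = max(P),
    inverse_difference = sum(P / (1 + abs(ii - jj))),
    imc1 = imc1,
    imc2 = imc2,
    idn = sum(P / (1 + abs(ii - jj) / Ng)),
    idmn = sum(P / (1 + (ii - jj)^2 / Ng^2)))
}

#' Extract the per-image feature vector
#'
#' Quantizes the in-mask pixels once to `Ng` levels, computes the
#' first-order histogram block on the quantized image, and the 20 Haralick
#' features for each of the four adjacency directions (0, 45, 90, 135
#' degrees) at distance `d`, returning the arithmetic mean per feature
#' across directions. A feature undefined in any direction is `NA` overall.
#' The unaveraged four-direction block is attached as attribute
#' `"per_direction"` (a directions x features matrix).
#'
#' @param img a [gray_image()].
#' @param mask logical analysis mask (`NULL` = all pixels).
#' @param Ng gray-level count (default 8).
#' @param d pair distance (default 1).
#' @param symmetric symmetric GLCM (default `TRUE`).
#' @param directions adjacency directions in degrees.
#' @param sum_variance_center passed to [haralick_features()].
#' @return Named numeric vector: 6 histogram features then 20
#'   direction-averaged GLCM features.
#' @export
extract_features <- function(img, mask = NULL, Ng = 8L, d = 1L,
                             symmetric = TRUE,
                             directions = c(0, 45, 90, 135),
                             sum_variance_center = "sum_average") {
  qimg <- quantize(img, mask, Ng)
  hist_block <- histogram_features(glcm_histogram(qimg))
  per_dir <- t(vapply(directions, function(ang) {
    haralick_features(compute_glcm(qimg, ang, d, symmetric),
                      sum_variance_center = sum_variance_center)
  }, numeric(20L)))
  rownames(per_dir) <- paste0("dir_", directions)
  avg <- colMeans(per_dir)       # NA propagates: undefined anywhere => NA
  out <- c(hist_block, avg)
  attr(out, "per_direction") <- per_dir
  out
}

#' Build the cohort feature table
#'
#' Runs [preprocess()] and [extract_features()] on every image of a cohort
#' and assembles the analysis table: one row per image with `image_id`,
#' `label` and one column per feature (undefined values as `NA`). With
#' `per_direction = TRUE` the unaveraged GLCM features are appended as
#' columns suffixed `_0`, `_45`, `_90`, `_135`.
#'
#' @param cohort an `ir_cohort` from [generate_cohort()], or a list of
#'   records each holding `image_id`, `image`, `label`.
#' @param pre_cfg a [preprocess_config()].
#' @param per_direction also emit direction-resolved columns.
#' @param ... passed to [extract_features()].
#' @return A data frame.
#' @export
extract_feature_table <- function(cohort, pre_cfg = preprocess_config(),
                                  per_direction = FALSE, ...) {
  rows <- lapply(cohort, function(rec) {
    pp <- preprocess(rec$image, pre_cfg)
    fv <- extract_features(pp$image, pp$mask, ...)
    row <- as.data.frame(as.list(fv))
    if (per_direction) {
      pd <- attr(fv, "per_direction")
      dir_tags <- sub("^dir_", "", rownames(pd))
      for (di in seq_len(nrow(pd))) {
        block <- as.list(pd[di, ])
        names(block) <- paste0(colnames(pd), "_", dir_tags[di])
        row <- cbind(row, as.data.frame(block))
      }
    }
    cbind(data.frame(image_id = rec$image_id, label = rec$label,
                     stringsAsFactors = FALSE), row)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
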