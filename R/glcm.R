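#' Quantize an image to Ng gray levels
#'
#' Uniform-width bins spanning the `[min, max]` of the in-mask intensities;
#' in-mask pixels map to levels `1..Ng` (the maximum maps to `Ng`),
#' masked-out pixels carry `NA`. The GLCM and the first-order histogram are
#' both computed on this shared intensity model.
#'
#' @param img a [gray_image()].
#' @param mask logical matrix (`TRUE` = analyze); `NULL` means all pixels.
#' @param Ng number of gray levels (>= 2).
#' @return A `quantized_image` list: `levels` (integer matrix with `NA`
#'   outside the mask), `Ng`, `bin_edges`.
#' @export
quantize <- function(img, mask = NULL, Ng = 8L) {
  stopifnot(is_gray_image(img))
  if (Ng < 2L) stop("Ng must be >= 2")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  if (!identical(dim(mask), dim(unclass(img)))) {
    stop("mask shape does not match image")
  }
  if (sum(mask) < 2L) stop("mask must contain at least 2 pixels")
  px <- unclass(img)
  vals <- px[mask]
  lo <- min(vals); hi <- max(vals)
  if (lo == hi) {
    warning("all in-mask pixels equal; quantizing to a single level")
    levels <- matrix(NA_integer_, nrow(img), ncol(img))
    levels[mask] <- 1L
    edges <- seq(lo, lo + 1, length.out = Ng + 1L)
  } else {
    edges <- seq(lo, hi, length.out = Ng + 1L)
    lv <- pmin(floor((px - lo) / (hi - lo) * Ng) + 1L, Ng)
    levels <- matrix(NA_integer_, nrow(img), ncol(img))
    levels[mask] <- as.integer(lv[mask])
  }
  structure(list(levels = levels, Ng = as.integer(Ng), bin_edges = edges),
            class = "quantized_image")
}

#' First-order intensity histogram
#'
#' Counts `h(i)` of in-mask pixels at each quantized level `i = 1..Ng` and
#' the probabilities `p(i) = h(i) / N` where `N` is the number of analyzed
#' pixels.
#'
#' @param qimg a [quantize()]d image.
#' @return An `intensity_histogram` list: `counts`, `probabilities`, `Ng`.
#' @export
glcm_histogram <- function(qimg) {
  stopifnot(inherits(qimg, "quantized_image"))
  lv <- qimg$levels[!is.na(qimg$levels)]
  if (length(lv) == 0L) stop("empty mask: no pixels to histogram")
  counts <- tabulate(lv, nbins = qimg$Ng)
  structure(list(counts = counts, probabilities = counts / sum(counts),
                 Ng = qimg$Ng),
            class = "intensity_histogram")
}

# Offset (drow, dcol) of the neighbor pixel for each adjacency direction,
# with matrix rows increasing downward: 0 deg = right, 45 deg = up-right,
# 90 deg = up, 135 deg = up-left.
glcm_offset <- function(direction, d) {
  switch(as.character(direction),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("direction must be one of 0, 45, 90, 135"))
}

# x * log(x) with the 0 * log 0 := 0 convention (natural log throughout).
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs (reference pixel, pixel at the direction's
#' offset at distance `d`) whose members are both in-mask, normalizes to a
#' probability matrix `P` with `P[i, j] = p(i, j)`, and precomputes the
#' marginals, moments and entropies the Haralick features are built from.
#' With `symmetric = TRUE` (Haralick's original definition) each pair is
#' also counted transposed, making `P` symmetric.
#'
#' @param qimg a [quantize()]d image.
#' @param direction adjacency direction in degrees: 0, 45, 90 or 135.
#' @param d pair distance in pixels (>= 1).
#' @param symmetric count each pair in both orders (default `TRUE`).
#' @return A `glcm` list: `P`, `direction`, `d`, `symmetric`, `pair_count`,
#'   marginals `px`, `py`, `p_xplusy` (indexed `k = 2..2Ng`), `p_xminusy`
#'   (indexed `k = 0..Ng-1`), moments `mu_x`, `mu_y`, `sigma_x`, `sigma_y`,
#'   and entropies `HX`, `HY`, `HXY`, `HXY1`, `HXY2` (natural log).
#' @export
compute_glcm <- function(qimg, direction = 0, d = 1L, symmetric = TRUE) {
  stopifnot(inherits(qimg, "quantized_image"))
  if (d < 1L) stop("distance d must be >= 1")
  off <- glcm_offset(direction, as.integer(d))
  lv <- qimg$levels
  h <- nrow(lv); w <- ncol(lv)
  r0 <- max(1L, 1L - off[1]); r1 <- min(h, h - off[1])
  c0 <- max(1L, 1L - off[2]); c1 <- min(w, w - off[2])
  if (r0 > r1 || c0 > c1) {
    stop("no valid pixel pairs for direction ", direction)
  }
  ref <- lv[r0:r1, c0:c1, drop = FALSE]
  nb <- lv[(r0:r1) + off[1], (c0:c1) + off[2], drop = FALSE]
  ok <- !is.na(ref) & !is.na(nb)
  if (!any(ok)) {
    stop("mask leaves no valid pixel pairs for direction ", direction)
  }
  Ng <- qimg$Ng
  counts <- tabulate(ref[ok] + (nb[ok] - 1L) * Ng, nbins = Ng * Ng)
  P <- matrix(counts, Ng, Ng)
  if (symmetric) P <- P + t(P)
  pair_count <- sum(P)
  P <- P / pair_count

  i <- seq_len(Ng)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(i * px); mu_y <- sum(i * py)
  sigma_x <- sqrt(sum((i - mu_x)^2 * px))
  sigma_y <- sqrt(sum((i - mu_y)^2 * py))

  ii <- matrix(i, Ng, Ng); jj <- t(ii)
  p_xplusy <- vapply(2:(2 * Ng),
                     function(k) sum(P[ii + jj == k]), 0)
  p_xminusy <- vapply(0:(Ng - 1L),
                      function(k) sum(P[abs(ii - jj) == k]), 0)

  HX <- -sum(xlogx(px)); HY <- -sum(xlogx(py)); HXY <- -sum(xlogx(P))
  pij <- outer(px, py)
  HXY1 <- -sum(P[P > 0] * log(pij[P > 0]))
  HXY2 <- -sum(xlogx(pij))

  structure(list(P = P, direction = direction, d = as.integer(d),
                 symmetric = symmetric, pair_count = pair_count,
                 Ng = Ng, px = px, py = py,
                 p_xplusy = p_xplusy, p_xminusy = p_xminusy,
                 mu_x = mu_x, mu_y = mu_y,
                 sigma_x = sigma_x, sigma_y = sigma_y,
                 HX = HX, HY = HY, HXY = HXY, HXY1 = HXY1, HXY2 = HXY2),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf(
    "<glcm> Ng = %d, direction = %s deg, d = %d, %s, %d pairs\n",
    x$Ng, format(x$direction), x$d,
    if (x$symmetric) "symmetric" else "asymmetric", x$pair_count))
  invisible(x)
}
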