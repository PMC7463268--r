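# Independent reference implementations used as oracles. Deliberately
# written as naive loops / literal formulas, sharing no code with the
# package internals they check.

# Median filter: per-pixel neighborhood collection with reflection padding,
# sorted, middle element taken.
oracle_median_filter <- function(m, k) {
  p <- (k - 1) %/% 2
  h <- nrow(m); w <- ncol(m)
  reflect <- function(idx, n) {
    idx <- ifelse(idx < 1, 2 - idx, idx)
    ifelse(idx > n, 2 * n - idx, idx)
  }
  out <- m
  for (r in seq_len(h)) {
    for (cl in seq_len(w)) {
      vals <- numeric(0)
      for (dr in -p:p) {
        for (dc in -p:p) {
          vals <- c(vals, m[reflect(r + dr, h), reflect(cl + dc, w)])
        }
      }
      sv <- sort(vals)
      out[r, cl] <- sv[(length(sv) + 1) / 2]
    }
  }
  out
}

# GLCM: brute-force enumeration of every ordered pixel pair at the offset.
oracle_glcm <- function(levels, Ng, direction, d, symmetric = TRUE) {
  off <- switch(as.character(direction),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  P <- matrix(0, Ng, Ng)
  h <- nrow(levels); w <- ncol(levels)
  for (r in seq_len(h)) {
    for (cl in seq_len(w)) {
      r2 <- r + off[1]; c2 <- cl + off[2]
      if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
      a <- levels[r, cl]; b <- levels[r2, c2]
      if (is.na(a) || is.na(b)) next
      P[a, b] <- P[a, b] + 1
      if (symmetric) P[b, a] <- P[b, a] + 1
    }
  }
  P / sum(P)
}

# Haralick features evaluated term by term from the probability matrix.
oracle_haralick <- function(P) {
  Ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mx <- sum((1:Ng) * px); my <- sum((1:Ng) * py)
  sx <- sqrt(sum(((1:Ng) - mx)^2 * px))
  sy <- sqrt(sum(((1:Ng) - my)^2 * py))
  psum <- sapply(2:(2 * Ng), function(k) {
    s <- 0
    for (i in 1:Ng) for (j in 1:Ng) if (i + j == k) s <- s + P[i, j]
    s
  })
  pdif <- sapply(0:(Ng - 1), function(k) {
    s <- 0
    for (i in 1:Ng) for (j in 1:Ng) if (abs(i - j) == k) s <- s + P[i, j]
    s
  })
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  acc <- con <- cor_num <- shd <- prm <- dis <- hom <- inv <- 0
  idn <- idmn <- eng <- maxp <- 0
  hxy1 <- hxy2 <- 0
  for (i in 1:Ng) {
    for (j in 1:Ng) {
      p <- P[i, j]
      acc <- acc + i * j * p
      con <- con + (i - j)^2 * p
      shd <- shd + (i + j - mx - my)^3 * p
      prm <- prm + (i + j - mx - my)^4 * p
      dis <- dis + abs(i - j) * p
      hom <- hom + p / (1 + (i - j)^2)
      inv <- inv + p / (1 + abs(i - j))
      idn <- idn + p / (1 + abs(i - j) / Ng)
      idmn <- idmn + p / (1 + (i - j)^2 / Ng^2)
      eng <- eng + p^2
      maxp <- max(maxp, p)
      if (p > 0) {
        cor_num <- cor_num + (i - mx) * (j - my) * p
        hxy1 <- hxy1 - p * log(px[i] * py[j])
      }
      if (px[i] * py[j] > 0) {
        hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j])
      }
    }
  }
  sa <- sum((2:(2 * Ng)) * psum)
  sent <- ent(psum)
  mdif <- sum((0:(Ng - 1)) * pdif)
  hx <- ent(px); hy <- ent(py); hxy <- ent(P)
  c(autocorrelation = acc,
    contrast = con,
    correlation = if (sx > 0 && sy > 0) cor_num / (sx * sy) else NA_real_,
    cluster_shade = shd,
    cluster_prominence = prm,
    dissimilarity = dis,
    homogeneity = hom,
    difference_variance = sum(((0:(Ng - 1)) - mdif)^2 * pdif),
    difference_entropy = ent(pdif),
    entropy = hxy,
    energy = eng,
    sum_average = sa,
    sum_entropy = sent,
    sum_variance = sum(((2:(2 * Ng)) - sa)^2 * psum),
    maximum_probability = maxp,
    inverse_difference = inv,
    imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_,
    imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    idn = idn,
    idmn = idmn)
}

# AUC as the tie-corrected Mann-Whitney U statistic over all
# (case, control) pairs, reported for the better-than-chance orientation.
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  u <- 0
  for (a in cs) for (b in ct) u <- u + (a > b) + 0.5 * (a == b)
  u <- u / (length(cs) * length(ct))
  max(u, 1 - u)
}

# Youden maximization by exhaustive search over every midpoint threshold
# and both orientations; returns the best J only (the package additionally
# applies documented tie-breaks to pick one cut-off).
oracle_youden_j <- function(scores, labels) {
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  n_case <- sum(labels == "case"); n_ctrl <- sum(labels == "control")
  best <- -Inf
  for (t in thr) {
    for (orient in c("gt", "le")) {
      pos <- if (orient == "gt") scores > t else scores <= t
      sens <- sum(pos & labels == "case") / n_case
      spec <- sum(!pos & labels == "control") / n_ctrl
      best <- max(best, sens + spec - 1)
    }
  }
  best
}

# Build a quantized_image directly from a level matrix (NA = masked out).
make_qimg <- function(levels, Ng) {
  structure(list(levels = levels, Ng = as.integer(Ng),
                 bin_edges = seq(0, 1, length.out = Ng + 1)),
            class = "quantized_image")
}

# Random labeled scores with ties for ROC tests.
random_score_set <- function(n_case, n_ctrl, n_distinct = 8) {
  labels <- c(rep("case", n_case), rep("control", n_ctrl))
  scores <- sample(seq_len(n_distinct), n_case + n_ctrl, replace = TRUE) +
    rnorm(n_case + n_ctrl, sd = 0.01) * rbinom(n_case + n_ctrl, 1, 0.5)
  list(scores = scores, labels = labels)
}

# Small fast cohort spec for tests (geometry scaled to 64x64 frames).
test_spec <- function(...) {
  args <- list(height = 64L, width = 64L, disc_radius = 8,
               disc_center_jitter = 4, vessel_count = 3L,
               lesion_count = 10L, lesion_radius_range = c(1.5, 4))
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_spec, args)
}

# Mean direction-averaged GLCM correlation of a background-only image.
background_correlation <- function(spec, group, seed, Ng = 8) {
  set.seed(seed)
  img <- make_background(spec, group)
  q <- quantize(img, Ng = Ng)
  mean(sapply(c(0, 45, 90, 135), function(a) {
    haralick_features(compute_glcm(q, a))["correlation"]
  }))
}
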