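#' One-way ANOVA F for a two-group feature
#'
#' The filter statistic used to rank features: the one-way ANOVA F
#' (`MS_between / MS_within`, df `(1, n - 2)`) between the case and control
#' values of one feature. Degenerate inputs follow a fixed policy: zero
#' within-group variance with distinct group means gives `F = Inf, p = 0`;
#' zero between-group variance gives `F = 0, p = 1`.
#'
#' @param values numeric feature values, one per image.
#' @param labels factor or character with exactly two groups, each
#'   contributing at least two finite values.
#' @return List with `F`, `p` and `means` (named per-group means).
#' @export
anova_f <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two groups required")
  ok <- is.finite(values)
  if (any(table(labels[ok]) < 2L)) {
    stop("each group needs at least 2 finite values")
  }
  values <- values[ok]; labels <- droplevels(labels[ok])
  means <- tapply(values, labels, mean)
  ss_within <- sum(tapply(values, labels,
                          function(v) sum((v - mean(v))^2)))
  if (ss_within == 0) {
    if (means[1] != means[2]) {
      return(list(F = Inf, p = 0, means = means))
    }
    return(list(F = 0, p = 1, means = means))
  }
  if (means[1] == means[2]) {
    return(list(F = 0, p = 1, means = means))
  }
  fit <- oneway.test(values ~ labels, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value), means = means)
}

#' Rank features by ANOVA F
#'
#' Computes [anova_f()] per feature column and orders features by
#' descending F (an infinite F ranks above every finite one); ties are
#' broken lexicographically by feature name. Features with any undefined
#' (`NA`/non-finite) value are excluded from ranking and listed in the
#' `"excluded"` attribute — they are never imputed.
#'
#' @param table feature data frame from [extract_feature_table()] (columns
#'   `image_id`, `label`, then features), or any data frame of numeric
#'   feature columns.
#' @param labels group labels; defaults to `table$label`.
#' @return A `ranked_features` data frame with columns `rank`, `feature`,
#'   `F`, `p`, `mean_control`, `mean_case`.
#' @export
rank_features <- function(table, labels = table$label) {
  feats <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                   c("image_id", "label"))
  if (length(feats) == 0L) stop("no numeric feature columns found")
  usable <- feats[vapply(feats, function(f) all(is.finite(table[[f]])),
                         TRUE)]
  if (length(usable) == 0L) stop("no feature with complete finite values")
  res <- lapply(usable, function(f) anova_f(table[[f]], labels))
  out <- data.frame(
    feature = usable,
    F = vapply(res, `[[`, 0, "F"),
    p = vapply(res, `[[`, 0, "p"),
    mean_control = vapply(res, function(r) unname(r$means["control"]), 0),
    mean_case = vapply(res, function(r) unname(r$means["case"]), 0),
    stringsAsFactors = FALSE)
  out <- out[order(-out$F, out$feature), ]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "excluded") <- setdiff(feats, usable)
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Keep the top-k ranked features
#'
#' @param ranked a [rank_features()] result.
#' @param k number of features to keep (default 5).
#' @return Character vector of the first `k` feature names in rank order.
#' @export
select_top_k <- function(ranked, k = 5L) {
  stopifnot(inherits(ranked, "ranked_features"))
  if (k < 1L || k > nrow(ranked)) {
    stop("k must be between 1 and ", nrow(ranked))
  }
  ranked$feature[seq_len(k)]
}
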