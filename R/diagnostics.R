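# Trapezoidal area under the (FPR, TPR) polyline.
trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2)
}

#' ROC curve of a score against the case/control label
#'
#' Candidate thresholds sit at the midpoints between consecutive sorted
#' unique scores, plus `-Inf` and `+Inf`, so a reported cut-off always falls
#' between observed values. Both orientations are evaluated — "positive if
#' score > t" (`gt_positive`) and "positive if score <= t" (`le_positive`)
#' — and the orientation with AUC >= 0.5 is reported. AUC is the trapezoidal
#' area under the (FPR, TPR) polyline, which equals the tie-corrected
#' Mann-Whitney U statistic divided by `n_case * n_control`. If all scores
#' are identical the ROC is degenerate: AUC 0.5, with a warning.
#'
#' @param scores numeric per-sample scores (finite).
#' @param labels `"case"` / `"control"` labels; both present. Cases are the
#'   positive class.
#' @return A `roc_result` list: `points` (data frame `threshold`,
#'   `sensitivity`, `specificity`, as proportions), `auc`, `orientation`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as_label_factor(labels)
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (nlevels(droplevels(labels)) < 2L) stop("both classes required")
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    warning("all scores identical; degenerate ROC with AUC = 0.5")
    thresholds <- c(-Inf, Inf)
  } else {
    thresholds <- c(-Inf, (head(u, -1) + tail(u, -1)) / 2, Inf)
  }
  n_case <- sum(labels == POSITIVE)
  n_ctrl <- sum(labels != POSITIVE)
  orient_points <- function(orientation) {
    pos <- if (orientation == "gt_positive") {
      lapply(thresholds, function(t) scores > t)
    } else {
      lapply(thresholds, function(t) scores <= t)
    }
    sens <- vapply(pos, function(p) sum(p & labels == POSITIVE), 0) / n_case
    spec <- vapply(pos, function(p) sum(!p & labels != POSITIVE), 0) / n_ctrl
    list(points = data.frame(threshold = thresholds, sensitivity = sens,
                             specificity = spec),
         auc = trapezoid_auc(1 - spec, sens))
  }
  gt <- orient_points("gt_positive")
  le <- orient_points("le_positive")
  chosen <- if (gt$auc >= le$auc) {
    c(gt, orientation = "gt_positive")
  } else {
    c(le, orientation = "le_positive")
  }
  chosen$all_points <- rbind(
    cbind(gt$points, orientation = "gt_positive"),
    cbind(le$points, orientation = "le_positive"))
  structure(chosen, class = "roc_result")
}

#' Youden-index optimal cut-off
#'
#' Maximizes `J = sensitivity + specificity - 1` over every
#' threshold/orientation pair of the ROC. Ties are broken toward higher
#' sensitivity (a screening setting misses cases at higher cost than it
#' flags controls), then toward the lower threshold, then toward the ROC's
#' reported orientation.
#'
#' @param roc a [roc_points()] result.
#' @return List with `cutoff`, `orientation` (of the cut-off rule),
#'   `sensitivity` and `specificity` (percent), `auc` (of the ROC's
#'   reported orientation) and `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  pts <- roc$all_points
  j <- pts$sensitivity + pts$specificity - 1
  best <- order(-j, -pts$sensitivity, pts$threshold,
                pts$orientation != roc$orientation)[1L]
  list(cutoff = pts$threshold[best],
       orientation = pts$orientation[best],
       sensitivity = 100 * pts$sensitivity[best],
       specificity = 100 * pts$specificity[best],
       auc = roc$auc,
       youden_j = j[best])
}

#' Per-feature diagnostic performance
#'
#' Applies [roc_points()] and [youden_cutoff()] to each feature column
#' independently and returns the per-feature cut-off table sorted by
#' descending AUC (the analog of a diagnostic-performance table for the
#' cohort at hand). Features with undefined values are skipped.
#'
#' @param table feature data frame.
#' @param labels group labels; defaults to `table$label`.
#' @param feature_names columns to analyze (`NULL` = all finite numeric
#'   features).
#' @return Data frame `feature`, `cutoff`, `orientation`, `sensitivity`,
#'   `specificity`, `auc`, `youden_j`, sorted by descending `auc` (ties by
#'   feature name).
#' @export
feature_diagnostics <- function(table, labels = table$label,
                                feature_names = NULL) {
  if (is.null(feature_names)) {
    feature_names <- setdiff(
      names(table)[vapply(table, is.numeric, TRUE)],
      c("image_id", "label"))
    feature_names <- feature_names[vapply(
      feature_names, function(f) all(is.finite(table[[f]])), TRUE)]
  }
  if (length(feature_names) == 0L) stop("no usable feature columns")
  rows <- lapply(feature_names, function(f) {
    yc <- youden_cutoff(roc_points(table[[f]], labels))
    data.frame(feature = f, cutoff = yc$cutoff,
               orientation = if (yc$orientation == "le_positive") "<=" else ">",
               sensitivity = yc$sensitivity, specificity = yc$specificity,
               auc = yc$auc, youden_j = yc$youden_j,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Group comparison of feature means
#'
#' Per-feature case/control means with the one-way ANOVA F and p-value — the
#' analog of a "texture parameters by group" summary table. Features with
#' undefined values are reported with `NA` statistics.
#'
#' @inheritParams feature_diagnostics
#' @return Data frame `feature`, `mean_control`, `mean_case`, `F`, `p` in
#'   table column order.
#' @export
group_comparison <- function(table, labels = table$label) {
  feats <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                   c("image_id", "label"))
  if (length(feats) == 0L) stop("no numeric feature columns found")
  labels <- as_label_factor(labels)
  rows <- lapply(feats, function(f) {
    v <- table[[f]]
    if (all(is.finite(v))) {
      a <- anova_f(v, labels)
      data.frame(feature = f,
                 mean_control = unname(a$means["control"]),
                 mean_case = unname(a$means["case"]),
                 F = a$F, p = a$p, stringsAsFactors = FALSE)
    } else {
      data.frame(feature = f,
                 mean_control = mean(v[labels == "control"]),
                 mean_case = mean(v[labels == "case"]),
                 F = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
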