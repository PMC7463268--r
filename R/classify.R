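# The ME case is the positive class everywhere in this module.
POSITIVE <- "case"
LABEL_LEVELS <- c("case", "control")

as_label_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), LABEL_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown labels: ", paste(bad, collapse = ", "))
  }
  factor(labels, levels = LABEL_LEVELS)
}

# z-score test rows with training-fold statistics; constant columns (sd = 0)
# pass through uncentered-scale 1 so they stay constant rather than NaN.
zscore_train_test <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2L, sd)
  sdv[sdv == 0] <- 1
  list(train = scale(train_x, center = mu, scale = sdv),
       test = scale(test_x, center = mu, scale = sdv))
}

#' Train a classifier and predict held-out samples
#'
#' Fits one of the three study classifiers on the training rows and predicts
#' the test rows. Features are z-scored with training-set statistics before
#' fitting (unstandardized distances/margins on mixed-scale texture features
#' are pathological). Decision scores (higher = more case-like) are returned
#' for ROC use.
#'
#' Classifiers: `svm_linear` — maximum-margin linear SVM with penalty `C`;
#' `knn` — majority vote among the `k` nearest training samples under
#' Euclidean distance, distance ties included deterministically by training
#' order, vote ties broken toward the alphabetically first label (`"case"`);
#' `naive_bayes` — Gaussian class-conditional independence model with
#' variance floor `var_floor`.
#'
#' @param train_x,test_x numeric matrices / data frames of feature rows.
#' @param train_y training labels (`"case"` / `"control"`; both present).
#' @param kind `"svm_linear"`, `"knn"` or `"naive_bayes"`.
#' @param C linear-SVM penalty (default 1).
#' @param k KNN neighborhood size (default 3).
#' @param var_floor Gaussian Naive Bayes variance floor (default 1e-9).
#' @return List with `labels` (factor of predictions) and `scores`
#'   (numeric; larger = more case-like).
#' @export
fit_predict <- function(train_x, train_y, test_x,
                        kind = c("svm_linear", "knn", "naive_bayes"),
                        C = 1, k = 3L, var_floor = 1e-9) {
  kind <- match.arg(kind)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- as_label_factor(train_y)
  if (nlevels(droplevels(train_y)) < 2L) {
    stop("training set must contain both classes")
  }
  z <- zscore_train_test(train_x, test_x)

  if (kind == "svm_linear") {
    fit <- e1071::svm(z$train, train_y, kernel = "linear", cost = C,
                      scale = FALSE)
    pr <- predict(fit, z$test, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # e1071 orients the decision value toward the first label of the
    # "a/b" column name; flip so that higher always means "case".
    first <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
    scores <- if (first == POSITIVE) dv else -dv
    labels <- factor(as.character(pr), levels = LABEL_LEVELS)
  } else if (kind == "knn") {
    k <- min(as.integer(k), nrow(z$train))
    pred <- apply(z$test, 1L, function(row) {
      dist2 <- colSums((t(z$train) - row)^2)
      nn <- order(dist2)[seq_len(k)]
      mean(train_y[nn] == POSITIVE)
    })
    # vote tie (0.5) goes to the alphabetically first label, "case"
    labels <- factor(ifelse(pred >= 0.5, POSITIVE, "control"),
                     levels = LABEL_LEVELS)
    scores <- as.numeric(pred)
  } else {
    df <- as.data.frame(z$train)
    fit <- e1071::naiveBayes(df, train_y)
    # enforce the variance floor on the per-class Gaussian sds
    fit$tables <- lapply(fit$tables, function(tb) {
      tb[, 2L] <- pmax(tb[, 2L], sqrt(var_floor)); tb
    })
    test_df <- as.data.frame(z$test)
    colnames(test_df) <- colnames(df)
    post <- predict(fit, test_df, type = "raw")
    scores <- post[, POSITIVE]
    labels <- factor(ifelse(scores >= 0.5, POSITIVE, "control"),
                     levels = LABEL_LEVELS)
  }
  list(labels = labels, scores = unname(scores))
}

confusion_report <- function(truth, predicted, scheme, classifier,
                             seed = NULL) {
  truth <- as_label_factor(truth)
  tp <- sum(truth == POSITIVE & predicted == POSITIVE)
  fn <- sum(truth == POSITIVE & predicted != POSITIVE)
  tn <- sum(truth != POSITIVE & predicted != POSITIVE)
  fp <- sum(truth != POSITIVE & predicted == POSITIVE)
  structure(list(
    scheme = scheme, classifier = classifier,
    predictions = as.character(predicted),
    TP = tp, FP = fp, TN = tn, FN = fn,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / length(truth),
    seed = seed), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> %s / %s: sens %.1f%%, spec %.1f%%, acc %.1f%% (TP %d FP %d TN %d FN %d)\n",
    x$classifier, x$scheme, x$sensitivity, x$specificity, x$accuracy,
    x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

# Resolve the feature-column matrix used for classification.
feature_matrix <- function(table, feature_names) {
  if (is.null(feature_names)) {
    feature_names <- setdiff(
      names(table)[vapply(table, is.numeric, TRUE)],
      c("image_id", "label"))
  }
  m <- as.matrix(table[, feature_names, drop = FALSE])
  if (any(!is.finite(m))) {
    stop("non-finite feature values; exclude undefined features first")
  }
  m
}

#' Leave-one-out cross-validation
#'
#' Holds out each sample in turn, fits on the remaining `n - 1` (z-scoring
#' refit per fold; with `nested = TRUE` the ANOVA ranking and top-k
#' selection are also refit per fold, avoiding selection bias), predicts the
#' held-out sample, and aggregates the confusion counts. If holding a
#' sample out leaves a single-class training fold (e.g. the only control of
#' a tiny cohort), that fold predicts the remaining class — the majority
#' vote any of the classifiers degenerates to without a second class.
#'
#' @param table feature data frame (see [extract_feature_table()]).
#' @param labels group labels; defaults to `table$label`.
#' @param kind classifier, see [fit_predict()].
#' @param feature_names columns to use (`NULL` = all finite numeric
#'   features; ignored when `nested = TRUE`).
#' @param nested refit feature selection inside each training fold.
#' @param top_k number of features kept when `nested = TRUE`.
#' @param ... passed to [fit_predict()].
#' @return A `classifier_report` (scheme `"loocv"`).
#' @export
loocv <- function(table, labels = table$label,
                  kind = "svm_linear", feature_names = NULL,
                  nested = FALSE, top_k = 5L, ...) {
  labels <- as_label_factor(labels)
  n <- nrow(table)
  if (n < 3L) stop("leave-one-out needs n >= 3")
  if (nlevels(droplevels(labels)) < 2L) stop("both classes required")
  preds <- character(n)
  for (i in seq_len(n)) {
    fold_train <- droplevels(labels[-i])
    if (nlevels(fold_train) == 1L) {
      preds[i] <- levels(fold_train)
      next
    }
    fold_feats <- feature_names
    if (nested) {
      ranked <- rank_features(table[-i, , drop = FALSE], labels[-i])
      fold_feats <- select_top_k(ranked, min(top_k, nrow(ranked)))
    }
    m <- feature_matrix(table, fold_feats)
    fp <- fit_predict(m[-i, , drop = FALSE], labels[-i],
                      m[i, , drop = FALSE], kind, ...)
    preds[i] <- as.character(fp$labels)
  }
  confusion_report(labels, factor(preds, levels = LABEL_LEVELS),
                   "loocv", kind)
}

#' Stratified split-half evaluation
#'
#' Seeded stratified split: per class, `ceil(fraction * n_class)` samples
#' train and the rest test. The classifier is fit once on the training part
#' and reported on the test part.
#'
#' @inheritParams loocv
#' @param fraction training fraction (default 0.5).
#' @param seed integer split seed.
#' @return A `classifier_report` (scheme `"split50"`).
#' @export
split_eval <- function(table, labels = table$label, kind = "svm_linear",
                       feature_names = NULL, fraction = 0.5, seed = 1L,
                       ...) {
  labels <- as_label_factor(labels)
  if (any(table(labels) < 2L)) {
    stop("each class needs >= 2 samples for a stratified split")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  train_idx <- unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    sample(idx, ceiling(fraction * length(idx)))
  }))
  m <- feature_matrix(table, feature_names)
  fp <- fit_predict(m[train_idx, , drop = FALSE], labels[train_idx],
                    m[-train_idx, , drop = FALSE], kind, ...)
  confusion_report(labels[-train_idx], fp$labels, "split50", kind,
                   seed = seed)
}
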