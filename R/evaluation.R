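#' Confusion-matrix and threshold-free performance metrics
#'
#' Computes the imbalance-aware metric suite from true binary labels and
#' positive-class scores: sensitivity Sn = TP/(TP+FN), specificity
#' Sp = TN/(TN+FP), accuracy Acc = (TP+TN)/N, Matthews correlation
#' Mcc = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), ROC-AUC
#' (trapezoidal, via pROC) and PR-AUC (precision-recall step integration).
#' A zero Mcc denominator is a degenerate confusion matrix; the convention
#' here is Mcc = 0 with an explicit warning and a `degenerate` flag rather
#' than a silent zero. With only one class present, Mcc and both AUCs are
#' reported as `NA` with the flag set.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores (higher = more positive), same length.
#' @param threshold Classification threshold on the scores (default 0.5).
#' @return A `metric_report`: list with `sn`, `sp`, `acc`, `mcc`, `roc_auc`,
#'   `pr_auc`, `threshold`, `counts` (tp/fp/tn/fn) and `degenerate`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)),
            !anyNA(scores))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  n <- length(labels)
  both_classes <- any(labels == 1L) && any(labels == 0L)

  sn <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  degenerate <- !both_classes || denom == 0
  mcc <- if (!both_classes) {
    NA_real_
  } else if (denom == 0) {
    warning("Mcc denominator is zero (degenerate confusion matrix); reporting 0")
    0
  } else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  }
  roc_auc <- if (both_classes) roc_auc_trapezoid(labels, scores) else NA_real_
  pr_auc <- if (both_classes) pr_auc_step(labels, scores) else NA_real_

  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc,
                 roc_auc = roc_auc, pr_auc = pr_auc,
                 threshold = threshold,
                 counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
                 degenerate = degenerate),
            class = "metric_report")
}

roc_auc_trapezoid <- function(labels, scores) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0L, 1L), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# Precision-recall area by step integration: walk thresholds from the
# highest score down (tied scores move together) and accumulate
# precision * (recall increment).
pr_auc_step <- function(labels, scores) {
  P <- sum(labels == 1L)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  keep <- c(sc[-length(sc)] != sc[-1L], TRUE)  # last index of each tie group
  tp <- cumsum(lab == 1L)[keep]
  fp <- cumsum(lab == 0L)[keep]
  recall <- tp / P
  precision <- tp / (tp + fp)
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

#' ROC and PR curve points for plotting
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores.
#' @return List of two data frames: `roc` (fpr, tpr) and `pr`
#'   (recall, precision), threshold-ordered.
#' @export
score_curves <- function(labels, scores) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  keep <- c(sc[-length(sc)] != sc[-1L], TRUE)
  tp <- c(0, cumsum(lab == 1L)[keep])
  fp <- c(0, cumsum(lab == 0L)[keep])
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  list(roc = data.frame(fpr = fp / N, tpr = tp / P),
       pr = data.frame(recall = (tp / P)[-1L],
                       precision = (tp / (tp + fp))[-1L]))
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Sn %.4f  Sp %.4f  Acc %.4f  Mcc %.4f  ROC %.4f  PRC %.4f (thr %.2f)\n",
              x$sn, x$sp, x$acc, x$mcc, x$roc_auc, x$pr_auc, x$threshold))
  with(x$counts, cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", tp, fp, tn, fn)))
  invisible(x)
}

#' Metric report as a flat JSON-ready list
#' @param report A `metric_report`.
#' @return Plain list mirroring the report fields.
#' @export
metrics_as_list <- function(report) {
  list(sn = report$sn, sp = report$sp, acc = report$acc, mcc = report$mcc,
       roc_auc = report$roc_auc, pr_auc = report$pr_auc,
       threshold = report$threshold, counts = report$counts)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `folds` folds, separately within each class
#' so class proportions are preserved; deterministic given `seed`.
#' @keywords internal
stratified_folds <- function(labels, folds, seed) {
  labels <- as.integer(labels)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  assignment <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < folds)
      stop(sprintf("class %d has %d samples, fewer than %d folds",
                   cls, length(idx), folds))
    assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assignment
}

#' Stratified k-fold cross-validation of a model factory
#'
#' Splits the data into stratified folds, fits the factory on each training
#' complement and scores the held-out fold. The headline report is computed
#' from the pooled out-of-fold scores (every sample scored exactly once by a
#' model that never saw it); per-fold reports are also returned because
#' repeated-run protocols average whole-run metrics.
#'
#' @param features Numeric matrix.
#' @param labels Binary 0/1 vector.
#' @param factory `function(features, labels, seed)` returning a fitted model
#'   accepted by [predict_proba()].
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment and per-fold fits.
#' @param threshold Classification threshold.
#' @return List: `pooled` (`metric_report`), `per_fold` (list of reports),
#'   `scores` (pooled OOF scores, original order), `fold` (assignment).
#' @export
kfold_cv <- function(features, labels, factory, folds = 10L, seed = 1L,
                     threshold = 0.5) {
  stopifnot(folds >= 2L)
  labels <- as.integer(labels)
  fold <- stratified_folds(labels, folds, seed)
  scores <- rep(NA_real_, length(labels))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    model <- factory(features[train_idx, , drop = FALSE], labels[train_idx],
                     seed = seed * 1000L + f)
    scores[test_idx] <- predict_proba(model, features[test_idx, , drop = FALSE])
    per_fold[[f]] <- compute_metrics(labels[test_idx], scores[test_idx],
                                     threshold)
  }
  list(pooled = compute_metrics(labels, scores, threshold),
       per_fold = per_fold, scores = scores, fold = fold)
}

#' Evaluate a fitted model on an independent test set
#'
#' Scores the test features and reports the metric suite at the given
#' threshold. The model carries a fingerprint of its training rows; if any
#' test row matches a training row the function warns about train/test
#' overlap (it cannot prove disjointness — callers own the split).
#'
#' @param model A fitted model accepted by [predict_proba()].
#' @param features Test feature matrix.
#' @param labels Test labels (0/1).
#' @param threshold Classification threshold (default 0.5).
#' @return A `metric_report` with the score vector attached as
#'   `attr(, "scores")`.
#' @export
independent_test <- function(model, features, labels, threshold = 0.5) {
  train_fp <- attr(model, "train_fingerprint")
  if (!is.null(train_fp)) {
    overlap <- sum(row_fingerprints(features) %in% train_fp)
    if (overlap > 0L)
      warning(sprintf("%d test row(s) also appear in the training data; independent-test metrics are optimistic", overlap))
  }
  scores <- predict_proba(model, features)
  report <- compute_metrics(as.integer(labels), scores, threshold)
  attr(report, "scores") <- scores
  report
}

row_fingerprints <- function(x) {
  apply(signif(unname(as.matrix(x)), 8), 1L, paste, collapse = ",")
}
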