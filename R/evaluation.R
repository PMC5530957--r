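check_binary <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must be aligned")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (sum(labels == 1L) == 0L) stop("no positive labels present")
  if (sum(labels == 0L) == 0L) stop("no negative labels present")
}

#' Confusion counts at a score threshold
#'
#' A site is predicted positive iff its score is at least `t`.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 ground-truth labels.
#' @param t Threshold.
#' @return Named numeric vector (TP, FP, TN, FN); the four counts
#'   partition the sample.
#' @export
confusion_at_threshold <- function(scores, labels, t) {
  check_binary(scores, labels)
  pred <- scores >= t
  c(TP = sum(pred & labels == 1L), FP = sum(pred & labels == 0L),
    TN = sum(!pred & labels == 0L), FN = sum(!pred & labels == 1L))
}

threshold_sweep <- function(scores, labels) {
  # cumulative TP/FP at each unique score threshold, descending; tied
  # scores collapse to a single threshold step
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  list(tp = cumsum(l)[last], fp = cumsum(1L - l)[last],
       thresholds = s[last],
       n_pos = sum(labels == 1L), n_neg = sum(labels == 0L))
}

#' ROC curve and AUC
#'
#' TPR = TP/(TP+FN) is plotted against FPR = FP/(FP+TN) at descending
#' unique score thresholds; the area is the trapezoidal sum, which for
#' tie-collapsed thresholds equals the Mann-Whitney pair-counting
#' statistic (ties between a positive and a negative earn half credit).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (both classes required).
#' @return List with `points` (data.frame fpr, tpr starting at (0,0) and
#'   ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  check_binary(scores, labels)
  sw <- threshold_sweep(scores, labels)
  fpr <- c(0, sw$fp / sw$n_neg)
  tpr <- c(0, sw$tp / sw$n_pos)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall curve and AUPR
#'
#' Points are taken at descending unique score thresholds; the area is the
#' piecewise-constant average-precision sum
#' `sum((recall_k - recall_{k-1}) * precision_k)` (no linear
#' interpolation).  The curve's first point inherits the precision of the
#' highest-score threshold rather than an arbitrary 1.0.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (both classes required).
#' @return List with `points` (data.frame recall, precision) and `aupr`.
#' @export
pr_aupr <- function(scores, labels) {
  check_binary(scores, labels)
  sw <- threshold_sweep(scores, labels)
  precision <- sw$tp / (sw$tp + sw$fp)
  recall <- sw$tp / sw$n_pos
  aupr <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(recall = c(0, recall),
                           precision = c(precision[1L], precision)),
       aupr = aupr)
}

#' Evaluate prediction scores against labels
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @param scenario Scenario tag recorded in the result (e.g. "self",
#'   "cross_tf").
#' @return An object of class `eval_result`: roc and pr point
#'   data.frames, `auc`, `aupr`, class counts and the scenario tag.
#' @export
evaluate_scores <- function(scores, labels, scenario = "unspecified") {
  roc <- roc_auc(scores, labels)
  pr <- pr_aupr(scores, labels)
  structure(list(roc = roc$points, pr = pr$points,
                 auc = roc$auc, aupr = pr$aupr,
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
                 scenario = scenario),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result [%s]: AUC %.4f, AUPR %.4f (%d pos / %d neg)\n",
              x$scenario, x$auc, x$aupr, x$n_pos, x$n_neg))
  invisible(x)
}

#' Aggregate evaluation results into a train-by-test matrix
#'
#' @param entries List of lists with fields `train`, `test` (tags) and
#'   `result` (an [evaluate_scores] result).
#' @return List with `auc` and `aupr` matrices (train tags as rows, test
#'   tags as columns; missing cells NA) plus `row_means` and `col_means`
#'   of the AUC matrix.
#' @export
summarize_matrix <- function(entries) {
  if (length(entries) == 0L) stop("no evaluation entries supplied")
  train <- vapply(entries, function(e) e$train, character(1))
  test <- vapply(entries, function(e) e$test, character(1))
  if (anyDuplicated(paste(train, test, sep = "\r")))
    stop("duplicate (train, test) pair in evaluation entries")
  rows <- unique(train); cols <- unique(test)
  auc <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
  aupr <- auc
  for (e in entries) {
    auc[e$train, e$test] <- e$result$auc
    aupr[e$train, e$test] <- e$result$aupr
  }
  list(auc = auc, aupr = aupr,
       row_means = rowMeans(auc, na.rm = TRUE),
       col_means = colMeans(auc, na.rm = TRUE))
}

#' Write an evaluation result as JSON
#' @param result An [evaluate_scores] result.
#' @param path Output file.
#' @export
write_eval_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Write an AUC/AUPR matrix as TSV
#' @param mat Matrix from [summarize_matrix] (`$auc` or `$aupr`).
#' @param path Output file.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(train = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
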