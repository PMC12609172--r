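#' Eight classification metrics for imbalanced synergy prediction
#'
#' Computes AUC-ROC and AUC-PR from the ranking of predicted probabilities
#' and six threshold metrics from the confusion matrix: accuracy, precision,
#' recall, F1, Cohen's kappa `(p_o - p_e) / (1 - p_e)` and balanced accuracy
#' `(TPR + TNR) / 2`. AUC-PR, kappa and BACC are the imbalance-aware subset.
#' With a single-class label vector the two AUCs are undefined and reported
#' as `NA` with `auc_defined = FALSE`.
#'
#' @param prob Predicted probability of the synergistic class.
#' @param labels 0/1 labels (1 = synergistic).
#' @param threshold Classification threshold for the confusion-matrix
#'   metrics (prediction is positive when `prob >= threshold`).
#' @return An object of class `metric_report`.
#' @examples
#' metric_report(c(0.9, 0.8, 0.3, 0.4, 0.2), c(1, 1, 1, 0, 0))
#' @export
metric_report <- function(prob, labels, threshold = 0.5) {
  stopifnot(length(prob) == length(labels), length(prob) > 0,
            all(labels %in% c(0, 1)))
  y <- as.integer(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  auc_defined <- n1 > 0L && n0 > 0L
  auc_roc <- if (auc_defined) auc_rank(prob, y) else NA_real_
  auc_pr <- if (auc_defined) average_precision(prob, y) else NA_real_

  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  nn <- length(y)
  acc <- (tp + tn) / nn
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / nn^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  tpr <- if (n1 > 0) tp / n1 else 0
  tnr <- if (n0 > 0) tn / n0 else 0
  bacc <- (tpr + tnr) / 2

  structure(list(auc_roc = auc_roc, auc_pr = auc_pr, acc = acc,
                 precision = precision, recall = recall, f1 = f1,
                 kappa = kappa, bacc = bacc, threshold = threshold,
                 auc_defined = auc_defined, n = nn, n_pos = n1),
            class = "metric_report")
}

# Mann-Whitney rank formulation of the ROC area (midranks handle ties)
auc_rank <- function(prob, y) {
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  r <- rank(prob)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision: step-wise integral of precision over recall, with one
# operating point per distinct predicted probability
average_precision <- function(prob, y) {
  o <- order(prob, decreasing = TRUE)
  ys <- y[o]
  ps <- prob[o]
  tp <- cumsum(ys)
  pos <- cumsum(rle(ps)$lengths)  # last index of each distinct threshold
  prec <- tp[pos] / pos
  rec <- tp[pos] / sum(ys)
  sum(diff(c(0, rec)) * prec)
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat(sprintf("Metric report (threshold %.2f, n = %d, positives = %d)\n",
              x$threshold, x$n, x$n_pos))
  m <- unlist(x[c("auc_roc", "auc_pr", "acc", "precision", "recall", "f1",
                  "kappa", "bacc")])
  print(round(m, digits))
  if (!x$auc_defined) cat("  (single-class labels: AUCs undefined)\n")
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(auc_roc = x$auc_roc, auc_pr = x$auc_pr, acc = x$acc,
             precision = x$precision, recall = x$recall, f1 = x$f1,
             kappa = x$kappa, bacc = x$bacc)
}

#' Class-weighted cross-entropy loss
#'
#' Mean over the batch of `-w(y) * log p(y)`, where `p(y)` is the predicted
#' probability of the true class and `w` the class weight. Probabilities are
#' clamped to `[1e-7, 1 - 1e-7]` before the logarithm. With unit weights
#' this is the ordinary binary cross-entropy.
#'
#' @param prob Predicted probability of the positive class.
#' @param labels 0/1 labels.
#' @param w_pos,w_neg Class weights (e.g. 2.3 and 1 to counter a 1:2.3
#'   positive:negative imbalance).
#' @return The scalar loss.
#' @examples
#' weighted_cross_entropy(c(0.5, 0.5), c(1, 0), w_pos = 2.3, w_neg = 1)
#' @export
weighted_cross_entropy <- function(prob, labels, w_pos = 1, w_neg = 1) {
  stopifnot(length(prob) == length(labels), all(labels %in% c(0, 1)))
  p_true <- ifelse(labels == 1, prob, 1 - prob)
  p_true <- pmin(pmax(p_true, 1e-7), 1 - 1e-7)
  w <- ifelse(labels == 1, w_pos, w_neg)
  mean(-w * log(p_true))
}
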