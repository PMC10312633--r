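# Classifier performance metrics, implemented from their definitions:
# recall = TP/(TP+FN), precision = TP/(TP+FP), f1 = harmonic mean, accuracy =
# correct/total, roc_auc from probability rankings, and the row-normalized
# (actual-by-predicted) confusion matrix.

#' Classifier performance report
#'
#' @param pred predicted class labels.
#' @param truth true class labels (same length).
#' @param prob optional probability of the positive class (binary case) for
#'   roc_auc.
#' @param positive positive class for the binary summary row (default the
#'   last factor level).
#' @return list(per_class, accuracy, roc_auc, confusion) where `per_class`
#'   has precision, recall and f1 per class and `confusion` rows (actual)
#'   sum to 1.
#' @export
classifierMetrics <- function(pred, truth, prob = NULL, positive = NULL) {
  if (length(pred) != length(truth)) stop("prediction/truth length mismatch")
  lev <- union(levels(factor(truth)), levels(factor(pred)))
  pred <- factor(pred, levels = lev)
  truth <- factor(truth, levels = lev)
  cm <- table(actual = truth, predicted = pred)
  per <- t(vapply(lev, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (isTRUE(precision + recall > 0)) {
      2 * precision * recall / (precision + recall)
    } else if (is.na(precision) || is.na(recall)) NA_real_ else 0
    c(precision = precision, recall = recall, f1 = f1)
  }, numeric(3)))
  per_class <- data.frame(class = lev, per, row.names = NULL)
  accuracy <- sum(diag(cm)) / sum(cm)
  roc_auc <- NA_real_
  if (!is.null(prob) && length(lev) == 2L) {
    pos <- if (is.null(positive)) lev[2L] else positive
    y <- truth == pos
    n1 <- sum(y); n0 <- sum(!y)
    if (n1 > 0 && n0 > 0) {
      r <- rank(prob)
      roc_auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  rs <- rowSums(cm)
  conf <- sweep(unclass(cm), 1L, ifelse(rs == 0, 1, rs), "/")
  list(per_class = per_class, accuracy = accuracy, roc_auc = roc_auc,
       confusion = conf)
}
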