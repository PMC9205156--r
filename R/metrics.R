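# Per-iteration classification metrics: recall, precision, F1 and the area
# under the ROC curve built from continuous decision scores.

#' ROC curve from continuous scores
#'
#' Thresholds sweep the distinct score values in decreasing order; tied
#' scores share a single ROC point.
#'
#' @param scores Continuous decision scores (higher = more fall-like).
#' @param truth True labels (`"fall"` / `"non_fall"`).
#' @return Data frame with `threshold`, `fpr`, `tpr`, beginning at (0, 0)
#'   and ending at (1, 1).
#' @export
roc_curve <- function(scores, truth) {
  pos <- truth == POSITIVE_CLASS
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stopf("ROC requires both classes in the truth labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  last <- cumsum(rep(1L, length(s)))[!duplicated(s, fromLast = TRUE)]
  # cumulative counts at each distinct threshold (ties collapsed)
  ctp <- cumsum(p)[last]
  cfp <- cumsum(!p)[last]
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, cfp / n_neg),
             tpr = c(0, ctp / n_pos))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of [roc_curve()]; equals the Mann-Whitney
#' pairwise-concordance statistic (ties counted half).
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  r <- roc_curve(scores, truth)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

#' Classification metrics of one test iteration
#'
#' Recall is the fraction of true falls detected among all true falls;
#' precision the fraction of true falls among events predicted as falls;
#' `F1 = 2 * recall * precision / (recall + precision)`.  Metrics whose
#' denominator is empty are flagged undefined (`NA`) rather than forced to a
#' value: precision when nothing is predicted fall, recall when no true falls
#' exist, AUC when the test set is single-class.  Undefined metrics are
#' excluded from report means and paired tests.
#'
#' @param scores Continuous decision scores.
#' @param predicted Predicted labels.
#' @param truth True labels.
#' @return An `iteration_metrics` list: confusion counts `tp`, `fp`, `fn`,
#'   `tn`; `recall`, `precision`, `f1`, `auc` (NA when undefined); and an
#'   `undefined` character vector naming flagged metrics.
#' @export
compute_metrics <- function(scores, predicted, truth) {
  if (!length(truth)) stopf("empty test set")
  if (length(scores) != length(truth) || length(predicted) != length(truth))
    stopf("scores, predicted and truth must have equal length")
  pos_t <- truth == POSITIVE_CLASS
  pos_p <- predicted == POSITIVE_CLASS
  tp <- sum(pos_p & pos_t); fp <- sum(pos_p & !pos_t)
  fn <- sum(!pos_p & pos_t); tn <- sum(!pos_p & !pos_t)
  undefined <- character()
  recall <- if (tp + fn > 0L) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); NA_real_ }
  precision <- if (tp + fp > 0L) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); NA_real_ }
  f1 <- if (is.na(recall) || is.na(precision)) {
    undefined <- c(undefined, "f1"); NA_real_
  } else if (recall + precision == 0) 0
  else 2 * recall * precision / (recall + precision)
  auc <- if (tp + fn > 0L && fp + tn > 0L) roc_auc(scores, truth) else {
    undefined <- c(undefined, "auc"); NA_real_ }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, recall = recall,
                 precision = precision, f1 = f1, auc = auc,
                 undefined = undefined),
            class = "iteration_metrics")
}
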