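#' @title ROC curves, AUC and Youden-index operating points
#' @description Empirical ROC construction under the convention "predict
#'   positive when score >= threshold" (pCR is the positive class), AUC by
#'   the trapezoidal rule, and operating-point metrics at the threshold
#'   maximising the Youden index J = sensitivity + specificity - 1. Ties in
#'   J resolve toward the higher (more specific) threshold.
#' @name evaluation
NULL

#' Empirical ROC curve
#'
#' Thresholds are the unique score values in descending order, preceded by a
#' point above every score (so the curve starts at (0, 0) and ends at
#' (1, 1)). The trapezoidal AUC over these points equals the Mann-Whitney
#' statistic with the 1/2 tie convention.
#'
#' @param scores Numeric class-1 scores (typically probabilities).
#' @param labels Binary outcome vector (1 = positive).
#' @return Object of class `roc_curve`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   and the class counts `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_curve")
}

#' Area under the ROC curve of a score vector
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) roc_curve(scores, labels)$auc

#' Youden index from sensitivity and specificity
#'
#' @param sensitivity,specificity Fractions in \[0, 1\].
#' @return J = sensitivity + specificity - 1.
#' @export
youden_j <- function(sensitivity, specificity) sensitivity + specificity - 1

#' Construct an operating point
#'
#' @param sensitivity,specificity,accuracy Fractions in \[0, 1\] (`accuracy`
#'   may be `NA` when unknown).
#' @param threshold Score cutoff (may be `Inf` for the degenerate
#'   predict-nothing-positive rule).
#' @return Object of class `operating_point` with `youden_j` filled in.
#' @export
operating_point <- function(sensitivity, specificity, accuracy = NA_real_,
                            threshold = NA_real_) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  structure(list(threshold = threshold, sensitivity = sensitivity,
                 specificity = specificity, accuracy = accuracy,
                 youden_j = youden_j(sensitivity, specificity)),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "<operating_point> threshold %.3g: sensitivity %.1f%%, specificity %.1f%%, accuracy %s, Youden J = %.3f\n",
    x$threshold, 100 * x$sensitivity, 100 * x$specificity,
    if (is.na(x$accuracy)) "NA" else sprintf("%.1f%%", 100 * x$accuracy),
    x$youden_j))
  invisible(x)
}

#' Youden-optimal operating point of a ROC curve
#'
#' Maximises J = tpr - fpr over the stored curve points (endpoints
#' included, so the optimum J is never negative); ties resolve to the
#' highest threshold.
#'
#' @param curve A [roc_curve()].
#' @return An [operating_point()].
#' @export
youden_optimal <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$tpr - curve$fpr
  i <- which.max(j)   # thresholds descend, so the first max is the highest
  n <- curve$n_pos + curve$n_neg
  acc <- (curve$tpr[i] * curve$n_pos + (1 - curve$fpr[i]) * curve$n_neg) / n
  operating_point(sensitivity = curve$tpr[i],
                  specificity = 1 - curve$fpr[i],
                  accuracy = acc,
                  threshold = curve$thresholds[i])
}

#' Operating-point metrics at a fixed threshold
#'
#' Sensitivity = TP/(TP+FN) over positives (pCR), specificity = TN/(TN+FP)
#' over negatives, accuracy = (TP+TN)/n, predicting positive when
#' score >= threshold.
#'
#' @inheritParams roc_curve
#' @param threshold Score cutoff.
#' @return An [operating_point()].
#' @export
operating_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L); fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L); fp <- sum(pred & labels == 0L)
  operating_point(sensitivity = tp / (tp + fn),
                  specificity = tn / (tn + fp),
                  accuracy = (tp + tn) / length(labels),
                  threshold = threshold)
}
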