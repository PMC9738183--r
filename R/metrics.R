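# Classifier evaluation: confusion metrics at a fixed cut plus the
# empirical ROC. REM is the positive class throughout.

#' Empirical ROC curve
#'
#' Sweeps every distinct score as a decision threshold (predict positive
#' when score >= threshold) and records one (FPR, TPR) point per threshold,
#' anchored at (0, 0) and (1, 1). Monotone non-decreasing in both
#' coordinates by construction.
#'
#' @param scores numeric positive-class probabilities/scores.
#' @param positive logical vector (TRUE = positive class), same length.
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
rocPoints <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  P <- sum(positive); N <- sum(!positive)
  if (P == 0L || N == 0L)
    stop("AUC undefined: reference contains a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(s[-1L] != s[-length(s)], TRUE)   # one point per distinct score
  data.frame(fpr = c(0, fp[last] / N, 1), tpr = c(0, tp[last] / P, 1))
}

# Trapezoidal area under an ROC polyline.
.trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
}

#' Evaluate staging scores against a reference hypnogram
#'
#' Computes the standard metric suite with REM as the positive class:
#' accuracy, precision, recall and F1 at the 0.5 probability cut, and AUC by
#' the trapezoidal rule over the empirical ROC. WAKE epochs in the reference
#' are mapped to REM (two-stage evaluation).
#'
#' @param remProb per-epoch REM probabilities.
#' @param ref reference [Hypnogram-class] or character stage labels.
#' @param threshold decision cut on the REM probability (default 0.5).
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `roc_points` (data.frame `fpr`, `tpr`) and `confusion` (2 x 2 table).
#' @export
evaluateStaging <- function(remProb, ref, threshold = 0.5) {
  if (is(ref, "Hypnogram")) ref <- stageLabels(ref)
  ref <- ifelse(ref == "WAKE", "REM", ref)
  stopifnot(length(remProb) == length(ref))
  pos <- ref == "REM"
  pred <- remProb >= threshold

  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_

  roc <- rocPoints(remProb, pos)
  list(accuracy = (tp + tn) / length(ref),
       precision = precision, recall = recall, f1 = f1,
       auc = .trapezoid(roc), roc_points = roc,
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(pred = c("REM", "NREM"),
                                          ref = c("REM", "NREM"))))
}
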