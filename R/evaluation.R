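# Classification / regression metric battery. Undefined denominators yield
# NA ("undefined"), never a silent 0: small-cohort evaluations would
# otherwise be corrupted.

#' Confusion counts
#'
#' @param TP,FP,TN,FN non-negative integer counts; their total must be
#'   positive.
#' @return a `ConfusionCounts` list.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(v < 0) || any(v != floor(v))) stopf("counts must be non-negative integers")
  if (sum(v) == 0) stopf("empty confusion table")
  structure(as.list(v), class = "ConfusionCounts")
}

#' Binarize paired scores against thresholds
#'
#' Predicted-positive iff `scores >= score_threshold`; truly-positive iff
#' `truth >= truth_threshold` (both inclusive; 42 is the conventional
#' scar-scale positivity cutoff).
#'
#' @param scores per-sample predicted values.
#' @param truth per-sample reference values.
#' @param score_threshold threshold on `scores`.
#' @param truth_threshold threshold on `truth`, default 42.
#' @return a [confusion_counts()].
#' @export
binarize_scores <- function(scores, truth, score_threshold,
                            truth_threshold = 42) {
  if (length(scores) == 0L) stopf("empty input")
  stopifnot(length(scores) == length(truth))
  pred <- scores >= score_threshold
  pos <- truth >= truth_threshold
  confusion_counts(TP = sum(pred & pos), FP = sum(pred & !pos),
                   TN = sum(!pred & !pos), FN = sum(!pred & pos))
}

#' Classification metrics from a confusion table
#'
#' Exact evaluation of the standard six formulas: accuracy, sensitivity,
#' specificity, precision, F1 = 2TP/(2TP+FP+FN), and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A metric
#' whose denominator is zero is returned as `NA` and listed in the
#' `"undefined"` attribute.
#'
#' @param cc a [confusion_counts()].
#' @return named numeric vector with attribute `"undefined"`.
#' @export
classification_metrics <- function(cc) {
  stopifnot(inherits(cc, "ConfusionCounts"))
  TP <- cc$TP; FP <- cc$FP; TN <- cc$TN; FN <- cc$FN
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  out <- c(accuracy = safe(TP + TN, TP + FP + TN + FN),
           sensitivity = safe(TP, TP + FN),
           specificity = safe(TN, TN + FP),
           precision = safe(TP, TP + FP),
           f1 = safe(2 * TP, 2 * TP + FP + FN),
           mcc = safe(TP * TN - FP * FN, mcc_den))
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' ROC and precision-recall curves with areas
#'
#' Threshold sweep over the unique score values (ties grouped at one
#' threshold, predicted-positive iff `score >= t`). The ROC area is the
#' trapezoid rule on (1 - specificity, sensitivity) — with grouped ties
#' this equals the normalized Mann-Whitney U statistic. The PR area uses
#' the step-wise precision envelope, `sum over thresholds of
#' (recall_k - recall_{k-1}) * precision_k`.
#'
#' @param scores numeric predictions.
#' @param labels logical (or 0/1) reference labels; both classes required.
#' @return list: `auc_roc`, `auc_pr`, `roc` (data.frame `fpr`, `tpr`),
#'   `pr` (data.frame `recall`, `precision`).
#' @export
roc_pr_curves <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  npos <- sum(labels)
  nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L) stopf("need both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(labels & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!labels & scores >= t), numeric(1))
  tpr <- c(0, tp / npos)
  fpr <- c(0, fp / nneg)
  auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / npos
  precision <- tp / (tp + fp)
  auc_pr <- sum(diff(c(0, recall)) * precision)
  list(auc_roc = auc_roc, auc_pr = auc_pr,
       roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = recall, precision = precision))
}

#' Regression metrics
#'
#' Pearson correlation, mean squared error and its square root. A constant
#' vector makes the correlation undefined (`NA`, flagged), never 0.
#'
#' @param y reference values.
#' @param yhat predicted values.
#' @return named numeric vector `pcc`, `mse`, `rmse` with attribute
#'   `"undefined"`.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  mse <- mean((y - yhat)^2)
  pcc <- if (stats::sd(y) == 0 || stats::sd(yhat) == 0) NA_real_
         else stats::cor(y, yhat)
  out <- c(pcc = pcc, mse = mse, rmse = sqrt(mse))
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Full metric battery for one evaluation run
#'
#' Binarizes predictions and truth at the given thresholds and reports the
#' classification metrics, both curve areas and the regression metrics in
#' one named vector.
#'
#' @param scores per-sample predictions (scar scale or expHRD scale).
#' @param truth per-sample reference scar values.
#' @param score_threshold threshold on `scores` for positivity.
#' @param truth_threshold threshold on `truth`, default 42.
#' @return a `MetricsReport` named numeric vector.
#' @export
metrics_report <- function(scores, truth, score_threshold,
                           truth_threshold = 42) {
  cc <- binarize_scores(scores, truth, score_threshold, truth_threshold)
  cls <- classification_metrics(cc)
  curves <- roc_pr_curves(scores, truth >= truth_threshold)
  reg <- regression_metrics(truth, scores)
  out <- c(cls, auc_roc = curves$auc_roc, auc_pr = curves$auc_pr, reg)
  attr(out, "undefined") <- c(attr(cls, "undefined"), attr(reg, "undefined"))
  class(out) <- "MetricsReport"
  out
}

#' @export
print.MetricsReport <- function(x, ...) {
  v <- unclass(x)
  attr(v, "undefined") <- NULL
  print(round(v, 4))
  und <- attr(x, "undefined")
  if (length(und)) cat("undefined:", paste(und, collapse = ", "), "\n")
  invisible(x)
}
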