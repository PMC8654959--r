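#' Confusion counts from binary label vectors
#'
#' Tallies the standard 2 x 2 table; the positive class is ACP = 1.
#'
#' @param truth,predicted Equal-length binary (0/1) vectors.
#' @return A [ConfusionCounts-class].
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))   # tp 1, fn 1, tn 1, fp 1
#' @export
confusionCounts <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted))
    .dataError("truth and predicted must have equal length")
  if (!all(c(truth, predicted) %in% c(0L, 1L)))
    .dataError("labels must be binary 0/1")
  new("ConfusionCounts",
      tp = sum(truth == 1L & predicted == 1L),
      tn = sum(truth == 0L & predicted == 0L),
      fp = sum(truth == 0L & predicted == 1L),
      fn = sum(truth == 1L & predicted == 0L))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: tp %d, tn %d, fp %d, fn %d\n", object@tp,
              object@tn, object@fp, object@fn))
})

#' Metric suite from confusion counts
#'
#' Accuracy, sensitivity, specificity and precision on the percent scale and
#' the Matthews correlation coefficient:
#' \deqn{Acc = 100 (tp+tn)/(tp+tn+fp+fn), \quad Sen = 100\, tp/(tp+fn),}
#' \deqn{Spe = 100\, tn/(tn+fp), \quad Pre = 100\, tp/(tp+fp),}
#' \deqn{MCC = (tp\,tn - fp\,fn)/\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}.}
#' When any marginal of the MCC denominator is zero the coefficient is
#' undefined; it is reported as 0 (the no-correlation convention).
#' Sensitivity/specificity/precision are `NaN` when their denominator is
#' empty.
#'
#' @param counts A [ConfusionCounts-class].
#' @param auc Optional AUC to record on the report.
#' @return An [EvaluationReport-class].
#' @examples
#' computeMetrics(new("ConfusionCounts", tp = 3L, tn = 4L, fp = 1L, fn = 2L))
#' @export
computeMetrics <- function(counts, auc = NA_real_) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- as.numeric(counts@tp); tn <- as.numeric(counts@tn)
  fp <- as.numeric(counts@fp); fn <- as.numeric(counts@fn)
  total <- tp + tn + fp + fn
  if (total == 0) .dataError("empty confusion table")
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  new("EvaluationReport",
      accuracy = (tp + tn) / total * 100,
      sensitivity = tp / (tp + fn) * 100,
      specificity = tn / (tn + fp) * 100,
      precision = tp / (tp + fp) * 100,
      mcc = mcc, auc = auc, counts = counts)
}

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(paste0("EvaluationReport: accuracy %.1f, sensitivity %.1f, ",
                     "specificity %.1f, precision %.1f, MCC %.2f%s\n"),
              object@accuracy, object@sensitivity, object@specificity,
              object@precision, object@mcc,
              if (!is.na(object@auc)) sprintf(", AUC %.2f", object@auc) else ""))
  cat(sprintf("  (tp %d, tn %d, fp %d, fn %d)\n", object@counts@tp,
              object@counts@tn, object@counts@fp, object@counts@fn))
})

#' ROC curve and AUC
#'
#' Standard ROC by threshold sweep over the distinct scores (predict
#' positive when score >= threshold), AUC by the trapezoid rule.  With the
#' half-credit-for-ties convention this equals the pairwise-concordance
#' (rank-statistic) AUC.
#'
#' @param truth Binary 0/1 vector containing both classes.
#' @param scores Positive-class scores in `[0, 1]`.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @examples
#' rocAuc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))$auc   # 0.75
#' @export
rocAuc <- function(truth, scores) {
  truth <- as.integer(truth); scores <- as.numeric(scores)
  if (length(truth) != length(scores))
    .dataError("truth and scores must have equal length")
  if (length(unique(truth)) < 2L)
    .dataError("ROC needs both classes in truth")
  P <- sum(truth == 1L); N <- sum(truth == 0L)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == 1L) / P, 1)
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == 0L) / N, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate scored predictions in one step
#'
#' Thresholds the scores (via [predictLabel()]), tallies the confusion
#' table, and returns the full metric report including AUC.
#'
#' @param truth Binary 0/1 vector.
#' @param scores Positive-class scores.
#' @param threshold Decision threshold, default 0.5.
#' @return An [EvaluationReport-class].
#' @export
evaluatePredictions <- function(truth, scores, threshold = 0.5) {
  auc <- if (length(unique(as.integer(truth))) >= 2L)
    rocAuc(truth, scores)$auc else NA_real_
  computeMetrics(confusionCounts(truth, predictLabel(scores, threshold)),
                 auc = auc)
}

#' One-row data frame view of a report
#'
#' @param report An [EvaluationReport-class].
#' @return Data frame with accuracy, sensitivity, specificity, precision,
#'   mcc and auc columns (full precision).
#' @export
reportRow <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  data.frame(accuracy = report@accuracy, sensitivity = report@sensitivity,
             specificity = report@specificity, precision = report@precision,
             mcc = report@mcc, auc = report@auc)
}
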