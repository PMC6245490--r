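#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(v >= 0), all(v == round(v)))
  structure(as.list(v), class = "confusion_counts")
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param cc A [confusion_counts()].
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(cc) {
  total <- cc$tp + cc$fp + cc$tn + cc$fn
  if (total == 0) stop("no evaluated samples", call. = FALSE)
  (cc$tp + cc$tn) / total
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; when any factor
#' of the denominator is zero the coefficient is undefined and 0 is
#' returned by convention.
#'
#' @param cc A [confusion_counts()].
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cc) {
  denom <- (cc$tp + cc$fp) * (cc$tp + cc$fn) *
           (cc$tn + cc$fp) * (cc$tn + cc$fn)
  if (denom == 0) return(0)
  (cc$tp * cc$tn - cc$fp * cc$fn) / sqrt(denom)
}

# pooled confusion counts from 0/1 truth and prediction vectors
.confusion_from <- function(truth, pred) {
  confusion_counts(
    tp = sum(truth == 1L & pred == 1L),
    fp = sum(truth == 0L & pred == 1L),
    tn = sum(truth == 0L & pred == 0L),
    fn = sum(truth == 1L & pred == 0L)
  )
}

# ROC-AUC of positive-class scores against 0/1 truth
.roc_auc <- function(truth, score) {
  if (length(unique(truth)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = score,
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
}

#' Five-number box summary of a metric series
#'
#' @param values Numeric vector (e.g. per-seed holdout accuracies).
#' @return List with `min`, `q1`, `median`, `q3`, `max`.
#' @export
box_summary <- function(values) {
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}
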