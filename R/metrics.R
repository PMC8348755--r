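# Evaluation metrics: confusion counts and the three standard indices
# (accuracy, sensitivity, specificity), with the seizure class as
# positive.

#' Confusion counts
#'
#' @param TP,FP,TN,FN non-negative integers: predictions of the seizure
#'   class that are correct (TP) / incorrect (FP), and predictions of the
#'   nonseizure class that are correct (TN) / incorrect (FN). At least one
#'   case is required.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  stopifnot(all(v >= 0), all(v == round(v)))
  if (sum(v) < 1) {
    stop_seiznet("confusion counts must describe at least one case",
                 "seiznet_validation_error")
  }
  structure(as.list(v), class = "confusion_counts")
}

#' Tally confusion counts from labels
#'
#' @param truth,pred factors or character vectors with levels
#'   `"nonseizure"` / `"seizure"`.
#' @return a [confusion_counts()].
#' @export
tally_confusion <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  confusion_counts(
    TP = sum(pred == "seizure" & truth == "seizure"),
    FP = sum(pred == "seizure" & truth == "nonseizure"),
    TN = sum(pred == "nonseizure" & truth == "nonseizure"),
    FN = sum(pred == "nonseizure" & truth == "seizure"))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Computes, in percent:
#' accuracy = (TP + TN) / (TP + TN + FP + FN) x 100,
#' sensitivity = TP / (TP + FN) x 100,
#' specificity = TN / (TN + FP) x 100.
#' A metric whose denominator is zero (no positive or no negative cases)
#' is undefined and reported as `NA`, never as 0.
#'
#' @param counts a [confusion_counts()].
#' @return an object of class `eval_result` with fields `counts`,
#'   `accuracy`, `sensitivity`, `specificity` (percent, full precision;
#'   printed to 2 decimals).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  p <- counts$TP + counts$FN
  n <- counts$TN + counts$FP
  structure(list(
    counts = counts,
    accuracy = (counts$TP + counts$TN) / total * 100,
    sensitivity = if (p > 0) counts$TP / p * 100 else NA_real_,
    specificity = if (n > 0) counts$TN / n * 100 else NA_real_
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("Accuracy %s, Sensitivity %s, Specificity %s (TP=%d FP=%d TN=%d FN=%d)\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
              x$counts$TP, x$counts$FP, x$counts$TN, x$counts$FN))
  invisible(x)
}
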