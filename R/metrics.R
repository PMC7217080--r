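#' Confusion matrix for binary solubility classification
#'
#' Class 1 ("soluble") is the positive class.  Either supply truth and
#' prediction vectors, or the four counts directly.
#'
#' @param truth,predicted Binary vectors (0/1) of equal length.
#' @param TP,TN,FP,FN Alternatively, non-negative integer counts.
#' @return Object of class `confusion_matrix`: named integer vector
#'   `c(TP, TN, FP, FN)`.
#' @examples
#' confusion_matrix(TP = 62, TN = 62, FP = 38, FN = 38)
#' @export
confusion_matrix <- function(truth = NULL, predicted = NULL,
                             TP = NULL, TN = NULL, FP = NULL, FN = NULL) {
  if (!is.null(truth)) {
    if (length(truth) != length(predicted))
      stopf("truth and predicted lengths differ")
    if (!is_binary_labels(truth) || !is_binary_labels(predicted))
      stopf("truth and predicted must be 0/1")
    TP <- sum(truth == 1 & predicted == 1)
    TN <- sum(truth == 0 & predicted == 0)
    FP <- sum(truth == 0 & predicted == 1)
    FN <- sum(truth == 1 & predicted == 0)
  }
  cm <- c(TP = as.integer(TP), TN = as.integer(TN),
          FP = as.integer(FP), FN = as.integer(FN))
  if (any(is.na(cm)) || any(cm < 0L)) stopf("counts must be non-negative")
  if (sum(cm) < 1L) stopf("confusion matrix is empty")
  structure(cm, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(x[c("TP", "FN", "FP", "TN")], 2L, 2L,
              dimnames = list(truth = c("1", "0"), predicted = c("1", "0")))
  print(m)
  a <- accuracy(x)
  mc <- tryCatch(mcc(x), error = function(e) NA_real_)
  cat(sprintf("accuracy %.3f, MCC %s\n", a,
              if (is.na(mc)) "undefined" else sprintf("%.3f", mc)))
  invisible(x)
}

as_cm <- function(x) {
  if (inherits(x, "confusion_matrix")) return(x)
  if (is.numeric(x) && setequal(names(x), c("TP", "TN", "FP", "FN")))
    return(confusion_matrix(TP = x[["TP"]], TN = x[["TN"]],
                            FP = x[["FP"]], FN = x[["FN"]]))
  stopf("expected a confusion_matrix or named TP/TN/FP/FN counts")
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP\,TN - FP\,FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' ranges over \[-1, 1\] and is the least class-imbalance-biased single
#' metric for binary classifiers.  It is undefined when any factor of
#' the denominator is zero (e.g. a classifier that never predicts one of
#' the classes); `mcc()` raises an error in that case, while internal
#' cross-validation code records such folds as missing.
#'
#' @param cm A [confusion_matrix()] (or named TP/TN/FP/FN vector).
#' @return MCC value.
#' @export
mcc <- function(cm) {
  cm <- as_cm(cm)
  v <- mcc_or_na(cm)
  if (is.na(v))
    stopf("MCC undefined: a denominator factor is zero (TP+FP=%d, TP+FN=%d, TN+FP=%d, TN+FN=%d)",
          cm[["TP"]] + cm[["FP"]], cm[["TP"]] + cm[["FN"]],
          cm[["TN"]] + cm[["FP"]], cm[["TN"]] + cm[["FN"]])
  v
}

# NA-returning variant used where undefined folds must be tolerated.
mcc_or_na <- function(cm) {
  tp <- as.numeric(cm[["TP"]]); tn <- as.numeric(cm[["TN"]])
  fp <- as.numeric(cm[["FP"]]); fn <- as.numeric(cm[["FN"]])
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / sqrt(den)
}

mcc_from_labels <- function(truth, predicted) {
  mcc_or_na(confusion_matrix(truth, predicted))
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @inheritParams mcc
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(cm) {
  cm <- as_cm(cm)
  (cm[["TP"]] + cm[["TN"]]) / sum(cm)
}

#' Median and (unscaled) median absolute deviation
#'
#' The MAD here is `median(|x - median(x)|)` without the usual 1.4826
#' normal-consistency factor: it is used as a robust spread summary of
#' model-repetition MCCs, not as a standard-deviation estimate.
#'
#' @param x Non-empty numeric vector; `NA`s are dropped.
#' @return Named numeric vector `c(median, mad)`.
#' @export
median_mad <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stopf("median_mad: no non-missing values")
  med <- stats::median(x)
  c(median = med, mad = stats::median(abs(x - med)))
}
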