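#' Confusion matrix for a binary reflux classification
#'
#' Counts, with positive = reflux limb (label 1): true positives (reflux
#' limbs correctly identified), false negatives (reflux limbs called
#' healthy), true negatives (healthy limbs correctly identified) and false
#' positives (healthy limbs given a reflux call).
#'
#' @param labels True binary labels (0/1 or logical).
#' @param predictions Predicted binary labels, same length.
#' @return A one-row tibble of class `confusion_matrix`: `tp, fn, tn, fp`.
#' @export
confusion_matrix <- function(labels, predictions) {
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  if (length(labels) != length(predictions)) {
    stop("labels and predictions must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L)) || !all(predictions %in% c(0L, 1L))) {
    stop("labels and predictions must be binary (0/1)", call. = FALSE)
  }
  out <- tibble(
    tp = sum(labels == 1L & predictions == 1L),
    fn = sum(labels == 1L & predictions == 0L),
    tn = sum(labels == 0L & predictions == 0L),
    fp = sum(labels == 0L & predictions == 1L))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Sensitivity, precision, accuracy and F-measure of a confusion matrix
#'
#' The four classification performance figures, each in percent:
#' sensitivity (recall, TPR) `= TP / (TP + FN)`, precision (PPV)
#' `= TP / (TP + FP)`, accuracy `= (TP + TN) / (TP + TN + FP + FN)`, and
#' the F-measure, the harmonic mean of precision and recall. A metric whose
#' denominator is zero is reported as `NA` (undefined), never silently 0.
#'
#' @param cm A [confusion_matrix()], or any one-row data frame / named list
#'   with non-negative counts `tp, fn, tn, fp` (not all zero).
#' @return A one-row tibble: the four counts plus `sensitivity`,
#'   `precision`, `accuracy`, `f_measure` in percent.
#' @examples
#' classification_metrics(list(tp = 26, fn = 0, tn = 11, fp = 4))
#' @export
classification_metrics <- function(cm) {
  cm <- as.list(cm)
  counts <- vapply(cm[c("tp", "fn", "tn", "fp")], function(x) as.numeric(x[1]),
                   numeric(1))
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("tp, fn, tn, fp must be non-negative counts", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("all-zero confusion matrix", call. = FALSE)
  tp <- counts[["tp"]]; fn <- counts[["fn"]]
  tn <- counts[["tn"]]; fp <- counts[["fp"]]
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- rate(tp, tp + fn)
  prec <- rate(tp, tp + fp)
  f <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_ else
    2 * sens * prec / (sens + prec)
  out <- tibble(tp = tp, fn = fn, tn = tn, fp = fp,
                sensitivity = sens, precision = prec,
                accuracy = 100 * (tp + tn) / total, f_measure = f)
  class(out) <- c("metrics_report", class(out))
  out
}
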