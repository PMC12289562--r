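round_half_up <- function(x, digits = 4L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Binary classification metrics
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 from 0/1
#' label and prediction vectors. Ratios with a zero denominator are reported
#' as 0 and flagged in `warnings`.
#'
#' @param labels,predictions equal-length 0/1 vectors.
#' @return list with the five metrics, the confusion counts, and `warnings`.
#' @export
compute_metrics <- function(labels, predictions) {
  if (length(labels) != length(predictions)) stop("length mismatch")
  tp <- sum(labels == 1 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  warn <- character()
  safe <- function(num, den, what) {
    if (den == 0) {
      warn <<- c(warn, sprintf("%s undefined (zero denominator); reported 0",
                               what))
      0
    } else {
      num / den
    }
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  specificity <- safe(tn, tn + fp, "specificity")
  f1 <- if (precision + recall == 0) {
    warn <- c(warn, "F1 undefined (precision + recall = 0); reported 0")
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = (tp + tn) / length(labels), precision = precision,
       recall = recall, specificity = specificity, f1 = f1,
       tp = tp, tn = tn, fp = fp, fn = fn, warnings = warn)
}

#' F1 from precision and recall
#'
#' Harmonic mean `2PR/(P+R)` rounded to the report precision (4 decimals,
#' half-up). Both inputs zero returns 0 with a warning.
#'
#' @param precision,recall values in `[0, 1]`.
#' @param digits report precision.
#' @return rounded F1.
#' @export
f1_from_pr <- function(precision, recall, digits = 4L) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) {
    warning("precision and recall both zero; F1 reported as 0")
    return(0)
  }
  round_half_up(2 * precision * recall / (precision + recall), digits)
}
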