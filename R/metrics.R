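#' Matthews correlation coefficient of a confusion matrix
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' ranges from -1 (perfectly wrong) through 0 (random) to +1 (perfect) and
#' weighs the positive and negative classes equally even when the dataset is
#' imbalanced. When any of the four marginal sums is zero the denominator
#' vanishes; such degenerate matrices are assigned MCC 0, the usual
#' convention, so one-sided classifiers remain comparable during grid search.
#'
#' @param tp,fp,tn,fn Non-negative counts (vectorized), or a data frame with
#'   columns `tp`, `fp`, `tn`, `fn` as the first argument.
#' @return Numeric vector of MCC values in `[-1, 1]`.
#' @export
#' @examples
#' mcc(tp = 50, fp = 0, tn = 50, fn = 0)  # +1
#' mcc(tp = 0, fp = 50, tn = 0, fn = 50)  # -1
mcc <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    cm <- tp
    tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  }
  check_counts(tp, fp, tn, fn)
  num <- tp * tn - fp * fn
  # factors kept separate to avoid integer overflow on large counts
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  out <- ifelse(den == 0, 0, num / den)
  as.numeric(out)
}

#' True positive rate, true negative rate, and accuracy
#'
#' \deqn{TPR = TP/(TP+FN), \quad TNR = TN/(TN+FP), \quad
#'   ACC = (TP+TN)/(TP+TN+FP+FN).}
#' The positive class is metamorphic throughout the package.
#'
#' @inheritParams mcc
#' @return A tibble with columns `tpr`, `tnr`, `acc`.
#' @export
rates <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    cm <- tp
    tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  }
  check_counts(tp, fp, tn, fn)
  if (any(tp + fn == 0)) {
    rlang::abort("TPR undefined: no positive (metamorphic) examples (tp + fn = 0)")
  }
  if (any(tn + fp == 0)) {
    rlang::abort("TNR undefined: no negative (monomorphic) examples (tn + fp = 0)")
  }
  tibble::tibble(
    tpr = tp / (tp + fn),
    tnr = tn / (tn + fp),
    acc = (tp + tn) / (tp + tn + fp + fn)
  )
}

check_counts <- function(tp, fp, tn, fn) {
  n <- c(length(tp), length(fp), length(tn), length(fn))
  if (any(n == 0)) rlang::abort("all four counts are required")
  counts <- c(tp, fp, tn, fn)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    rlang::abort("confusion-matrix counts must be non-negative finite numbers")
  }
  if (any(tp + fp + tn + fn == 0)) {
    rlang::abort("confusion matrix is empty (all counts zero)")
  }
  invisible(TRUE)
}
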