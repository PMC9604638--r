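#' Build a binary confusion matrix from predictions and truth
#'
#' Counts follow the risk-prediction convention: the positive class is the
#' high-risk day (`ClassRisk`), so TP counts risk days predicted as risk.
#'
#' @param predicted logical or 0/1 vector of predicted classes (TRUE = risk).
#' @param actual logical or 0/1 vector of observed classes (TRUE = risk).
#' @return An object of class `confusion_matrix`: a list with integer counts
#'   `tp`, `fn`, `fp`, `tn` and `n`.
#' @export
confusion_matrix <- function(predicted, actual) {
  predicted <- as.logical(predicted)
  actual <- as.logical(actual)
  if (length(predicted) != length(actual)) {
    stop("'predicted' and 'actual' must have the same length")
  }
  if (anyNA(predicted) || anyNA(actual)) {
    stop("missing values in predicted or actual classes")
  }
  cm <- list(
    tp = sum(predicted & actual),
    fn = sum(!predicted & actual),
    fp = sum(predicted & !actual),
    tn = sum(!predicted & !actual)
  )
  cm$n <- cm$tp + cm$fn + cm$fp + cm$tn
  class(cm) <- "confusion_matrix"
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
    dimnames = list(
      actual = c("risk", "noRisk"),
      predicted = c("risk", "noRisk")
    )
  )
  print(m)
  invisible(x)
}

#' Confusion-matrix performance metrics
#'
#' Computes the balanced ("weighted") accuracy, sensitivity, specificity,
#' precision and F1 score of a binary classifier. Weighted accuracy is the
#' mean of sensitivity and specificity, i.e. TP/(2(TP+FN)) + TN/(2(TN+FP)).
#' A metric whose denominator is zero is flagged undefined and reported as
#' `NA` rather than `NaN`.
#'
#' @param cm a `confusion_matrix`, or a list/vector with elements
#'   `tp`, `fn`, `fp`, `tn`.
#' @param literal_printed logical; if `TRUE` use the literal published
#'   variant specificity = TN/(FP+FN) instead of the standard TN/(TN+FP).
#'   Provided for auditability only; the default is the standard definition,
#'   which is also the one consistent with the weighted-accuracy formula.
#' @return An object of class `metrics_report`: a list with elements
#'   `weighted_accuracy`, `sensitivity`, `specificity`, `precision`, `f1`
#'   and a character vector `undefined` naming any flagged metrics.
#' @export
compute_metrics <- function(cm, literal_printed = FALSE) {
  cm <- as.list(cm)
  counts <- vapply(cm[c("tp", "fn", "fp", "tn")], function(v) as.double(v), 0)
  if (anyNA(counts)) stop("confusion matrix needs tp, fn, fp, tn counts")
  if (any(counts < 0)) stop("confusion-matrix counts must be non-negative")
  tp <- counts[["tp"]]; fn <- counts[["fn"]]
  fp <- counts[["fp"]]; tn <- counts[["tn"]]
  if (tp + fn + fp + tn < 1) stop("empty confusion matrix")

  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec_den <- if (literal_printed) fp + fn else tn + fp
  spec <- safe_div(tn, spec_den, "specificity")
  prec <- safe_div(tp, tp + fp, "precision")
  f1 <- if (is.na(sens) || is.na(prec)) {
    undefined <- c(undefined, "f1")
    NA_real_
  } else if (prec + sens == 0) {
    undefined <- c(undefined, "f1")
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  wacc <- if (is.na(sens) || is.na(spec)) {
    undefined <- c(undefined, "weighted_accuracy")
    NA_real_
  } else {
    tp / (2 * (tp + fn)) + tn / (2 * (tn + fp))
  }
  out <- list(
    weighted_accuracy = wacc,
    sensitivity = sens,
    specificity = spec,
    precision = prec,
    f1 = f1,
    undefined = unique(undefined)
  )
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  vals <- unlist(x[c(
    "weighted_accuracy", "sensitivity", "specificity",
    "precision", "f1"
  )])
  if (!is.null(x$roc_auc)) vals <- c(vals, roc_auc = x$roc_auc)
  print(round(vals, digits))
  if (length(x$undefined)) {
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability P(score_pos > score_neg) +
#' 0.5 P(tie), either via the rank-sum formula (default) or by explicit
#' pairwise comparison; the two are algebraically identical.
#'
#' @param scores numeric risk scores (higher = more risk-like).
#' @param labels logical or 0/1 observed classes (TRUE = positive/risk).
#' @param method `"rank"` or `"pairwise"`.
#' @return AUC in \[0, 1\], or `NA` with a warning when only one class is
#'   present.
#' @export
roc_auc <- function(scores, labels, method = c("rank", "pairwise")) {
  method <- match.arg(method)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    warning("ROC AUC undefined: only one class present")
    return(NA_real_)
  }
  if (method == "rank") {
    r <- rank(scores, ties.method = "average")
    (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  } else {
    pos <- scores[labels]
    neg <- scores[!labels]
    wins <- outer(pos, neg, ">")
    ties <- outer(pos, neg, "==")
    (sum(wins) + 0.5 * sum(ties)) / (n_pos * n_neg)
  }
}

#' Relative improvement of one metric over a baseline, in percent
#'
#' @param base baseline metric value (must be positive).
#' @param improved metric value of the improved method.
#' @param digits decimals to round the percentage to (default 1, the usual
#'   reporting precision).
#' @return `100 * (improved - base) / base`, rounded.
#' @export
relative_improvement <- function(base, improved, digits = 1) {
  if (!is.numeric(base) || !is.numeric(improved)) stop("numeric inputs required")
  if (any(base <= 0)) stop("'base' must be positive")
  round(100 * (improved - base) / base, digits)
}
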