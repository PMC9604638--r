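#' Reported classifier performance of the original study cohort
#'
#' Average test-set performance over the 19 adult asthma patients of the
#' original monitoring study (whose clinical data are not publicly
#' available), for the stand-alone logistic regression and the
#' transfer-learning pipeline, both trained with SMOTE. Shipped so the
#' relative-improvement arithmetic can be cross-checked and so synthetic
#' results have a published point of comparison.
#'
#' @return data frame with one row per method and the six reported metrics.
#' @export
reference_classifier_performance <- function() {
  data.frame(
    method = c("lr", "tllr"),
    weighted_accuracy = c(0.645, 0.738),
    sensitivity = c(0.614, 0.727),
    specificity = c(0.679, 0.757),
    precision = c(0.607, 0.687),
    f1 = c(0.596, 0.689),
    roc_auc = c(0.618, 0.741),
    stringsAsFactors = FALSE
  )
}

#' Reported quantile-regression calibration errors of the original cohort
#'
#' Mean Err_tau of the per-patient sliding-window quantile models of the
#' original 19-patient study, by tau band (rows) and training-window size
#' in days (columns), all with a 7-day model-usage period. Used to
#' cross-check the marginal-average machinery of
#' [summarize_err_table()].
#'
#' @return 10 x 4 numeric matrix; rownames are tau bands, colnames are
#'   training sizes.
#' @export
reference_qr_error_table <- function() {
  cells <- c(
    0.092, 0.103, 0.118, 0.037,
    0.057, 0.112, 0.068, 0.042,
    0.019, 0.053, 0.021, 0.032,
    0.030, 0.015, 0.016, 0.012,
    0.030, 0.009, 0.025, 0.045,
    0.033, 0.050, 0.048, 0.078,
    0.046, 0.101, 0.071, 0.055,
    0.111, 0.105, 0.100, 0.056,
    0.143, 0.157, 0.152, 0.113,
    0.173, 0.169, 0.145, 0.153
  )
  matrix(cells, 10, 4,
    byrow = TRUE,
    dimnames = list(tau_bands()$label, c("30", "35", "45", "50"))
  )
}
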