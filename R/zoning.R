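#' Patient-specific critical PEFR value
#'
#' The critical value PEFR_C divides a patient's own historical morning PEFR
#' distribution into a safe zone (upper 1 - q) and a risk zone (lower q).
#' It is the empirical q-quantile computed with linear interpolation between
#' order statistics (the common "type 7" convention, h = (n - 1) q + 1),
#' chosen for continuity in q; other conventions can be passed through
#' `type`.
#'
#' @param history numeric vector of historical AM PEFR values (L/min).
#' @param q risk-zone quantile in (0, 1); default 0.20 (lower 20 percent).
#' @param min_history smallest usable history length (default 10).
#' @param type quantile convention passed to [stats::quantile()].
#' @return An object of class `risk_zoning`: list with `pefr_critical`,
#'   `cutoff_quantile`, `history_n`.
#' @export
critical_pefr <- function(history, q = 0.20, min_history = 10, type = 7) {
  history <- history[!is.na(history)]
  if (length(history) < min_history) {
    stop(sprintf(
      "insufficient PEFR history: %d values (< %d required)",
      length(history), min_history
    ))
  }
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    stop("'q' must be a single fraction in (0, 1)")
  }
  z <- list(
    pefr_critical = unname(stats::quantile(history, probs = q, type = type)),
    cutoff_quantile = q,
    history_n = length(history)
  )
  class(z) <- "risk_zoning"
  z
}

#' @export
print.risk_zoning <- function(x, ...) {
  cat(sprintf(
    "Risk zoning: PEFR_C = %.1f L/min (lower %.0f%% of %d historical values)\n",
    x$pefr_critical, 100 * x$cutoff_quantile, x$history_n
  ))
  invisible(x)
}

#' Label patient-days as risk / no-risk against the critical PEFR value
#'
#' A day is a risk day iff its observed AM PEFR is strictly below PEFR_C
#' (the boundary value itself is safe). Rows with a missing PEFR are
#' dropped.
#'
#' @param rows data frame of daily feature rows (see [build_feature_table()]);
#'   must carry the AM PEFR in the column named by `pefr_col`.
#' @param zoning a `risk_zoning` object from [critical_pefr()], or `NULL`
#'   to estimate it from `rows[[pefr_col]]` itself.
#' @param pefr_col name of the column holding the day's observed AM PEFR.
#' @return `rows` with logical column `label` (TRUE = risk) and numeric
#'   column `pefr_critical` appended; attribute `n_dropped` counts rows
#'   removed for missing PEFR.
#' @export
label_days <- function(rows, zoning = NULL, pefr_col = "am_pefr") {
  if (!pefr_col %in% names(rows)) {
    stop(sprintf("column '%s' not found", pefr_col))
  }
  if (is.null(zoning)) {
    zoning <- critical_pefr(rows[[pefr_col]])
  }
  stopifnot(inherits(zoning, "risk_zoning"))
  keep <- !is.na(rows[[pefr_col]])
  out <- rows[keep, , drop = FALSE]
  out$label <- out[[pefr_col]] < zoning$pefr_critical
  out$pefr_critical <- zoning$pefr_critical
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "zoning") <- zoning
  out
}
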