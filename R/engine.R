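#' Decision-engine configuration
#'
#' Both decision parameters are deliberately explicit in the printed
#' config: the critical quantile `tau_c` (default 0.2, aligned with the
#' risk-zoning cutoff) and the alert threshold `theta` on the day-to-day
#' drop of the predicted critical quantile. When `theta` is not given it is
#' resolved as 5% of the patient's median PEFR, which therefore must be
#' supplied.
#'
#' @param tau_c critical quantile in (0, 1); must be on the QR grid.
#' @param theta drop threshold in L/min (`>= 0`), or `NULL` to use
#'   `0.05 * median_pefr`.
#' @param median_pefr the patient's median PEFR (L/min); required when
#'   `theta` is `NULL`.
#' @param threshold classification probability threshold (default 0.5).
#' @param update_hooks named list of callbacks invoked with each decision
#'   outcome; the default is none (no update rule is applied silently).
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(tau_c = 0.2, theta = NULL, median_pefr = NULL,
                          threshold = 0.5, update_hooks = list()) {
  if (tau_c <= 0 || tau_c >= 1) stop("tau_c must be in (0, 1)")
  if (is.null(theta)) {
    if (is.null(median_pefr)) {
      stop("supply 'theta' explicitly or 'median_pefr' to derive it (5% rule)")
    }
    theta <- 0.05 * median_pefr
  }
  if (!is.numeric(theta) || theta < 0) stop("theta must be >= 0")
  structure(
    list(
      tau_c = tau_c, theta = theta, threshold = threshold,
      update_hooks = update_hooks
    ),
    class = "engine_config"
  )
}

#' @export
print.engine_config <- function(x, ...) {
  cat(sprintf(
    "Engine config: tau_c = %.2f, theta = %.1f L/min, classification threshold = %.2f, %d update hook(s)\n",
    x$tau_c, x$theta, x$threshold, length(x$update_hooks)
  ))
  invisible(x)
}

#' Daily two-model decision
#'
#' The daily procedure: (1) the classifier predicts the next-day risk
#' class; if the probability is below the threshold the quantile model is
#' not consulted and a no-risk report is emitted. (2-3) Otherwise the
#' quantile model predicts PEFR at the critical quantile `tau_c`. (4) If
#' that prediction has dropped from its previous value by more than
#' `theta`, the alert flag is set. A report is always emitted; update
#' hooks receive the step outcomes.
#'
#' @param clf trained classifier (`tl_classifier` or `plain_lr`).
#' @param qr_model a `sliding_qr` model.
#' @param today_features one feature row (data frame) for today.
#' @param previous_pefr_tau_c the critical-quantile prediction from the
#'   most recent day on which the quantile model was consulted, or `NA`.
#' @param config an [engine_config()].
#' @return An object of class `prediction_report`: list with `date`,
#'   `class` (`"risk"`/`"noRisk"`), `probability`, `pefr_tau_c`,
#'   `previous_pefr_tau_c`, `drop`, `alert`, `qr_consulted`.
#' @export
daily_decision <- function(clf, qr_model, today_features,
                           previous_pefr_tau_c = NA_real_,
                           config = engine_config(theta = 20)) {
  stopifnot(inherits(config, "engine_config"))
  pr <- predict_risk(clf, today_features)
  p <- pr$probability[1]
  report <- list(
    date = if ("date" %in% names(today_features)) today_features$date[1] else NA,
    class = "noRisk", probability = p,
    pefr_tau_c = NA_real_, previous_pefr_tau_c = previous_pefr_tau_c,
    drop = NA_real_, alert = FALSE, qr_consulted = FALSE
  )
  if (p >= config$threshold) {
    report$class <- "risk"
    report$qr_consulted <- TRUE
    q <- predict_quantile(
      qr_model, today_features[1, , drop = FALSE], config$tau_c
    )
    report$pefr_tau_c <- as.numeric(q)
    if (is.na(previous_pefr_tau_c)) {
      warning("no previous PEFR(tau_c) available; drop undefined, no alert")
    } else {
      report$drop <- previous_pefr_tau_c - report$pefr_tau_c
      report$alert <- report$pefr_tau_c < previous_pefr_tau_c &&
        report$drop > config$theta
    }
  }
  class(report) <- "prediction_report"
  for (hook in config$update_hooks) hook(report)
  report
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf(
    "%s: %s (p = %.2f)%s%s\n",
    format(x$date), x$class, x$probability,
    if (x$qr_consulted) sprintf(", PEFR(tau_c) = %.1f", x$pefr_tau_c) else "",
    if (isTRUE(x$alert)) sprintf(" ALERT (drop %.1f)", x$drop) else ""
  ))
  invisible(x)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates (or accepts) a cohort, builds and labels the daily feature
#' tables, evaluates the stand-alone LR and TL + LR classifiers per target
#' patient under the leave-one-patient-out 80/20 protocol, runs the
#' sliding-window quantile model per target, and replays the daily decision
#' procedure over each target's final model-usage block. Seed-reproducible
#' end to end.
#'
#' @param x a [cohort_config()] or an existing `synthetic_cohort`.
#' @param targets patient ids to evaluate (default: all).
#' @param seed seed for model training and splits.
#' @param run_classifier,run_qr stage switches.
#' @param window a [window_spec()] for the quantile model.
#' @param taus quantile grid.
#' @param source_args extra arguments for [train_source_model()].
#' @param out_dir optional directory; artifacts are written as CSV/JSON.
#' @return An object of class `pefr_run`: list with `metrics` (one row per
#'   patient and method), `qr_errors`, `reports`, `manifest`.
#' @export
run_pipeline <- function(x, targets = NULL, seed = 1, run_classifier = TRUE,
                         run_qr = TRUE, window = window_spec(),
                         taus = default_tau_grid(), source_args = list(),
                         out_dir = NULL) {
  cohort <- if (inherits(x, "cohort_config")) simulate_cohort(x) else x
  stopifnot(inherits(cohort, "synthetic_cohort"))
  features <- build_cohort_features(cohort)
  ids <- unique(features$patient_id)
  if (is.null(targets)) targets <- ids

  metrics_rows <- list()
  qr_rows <- list()
  reports <- list()
  for (id in targets) {
    rows <- features[features$patient_id == id, , drop = FALSE]
    ev <- NULL
    if (run_classifier && length(ids) > 1) {
      ev <- evaluate_patient(features, id, seed = seed, source_args = source_args)
      for (m in c("lr", "tllr")) {
        mm <- ev[[m]]$metrics
        metrics_rows[[paste(id, m)]] <- data.frame(
          patient_id = id, method = m,
          weighted_accuracy = mm$weighted_accuracy,
          sensitivity = mm$sensitivity, specificity = mm$specificity,
          precision = mm$precision, f1 = mm$f1, roc_auc = mm$roc_auc
        )
      }
    }
    if (run_qr && nrow(rows) > window$W) {
      run <- sliding_window_run(rows, window, taus = taus)
      s <- summary(run)
      qr_rows[[id]] <- data.frame(patient_id = id, s)
      if (run_classifier && !is.null(ev)) {
        cfgd <- engine_config(median_pefr = stats::median(rows$am_pefr))
        last <- run$iterations[[length(run$iterations)]]
        days <- last$predict[1]:last$predict[2]
        prev <- NA_real_
        day_reports <- list()
        for (d in days) {
          rep_d <- suppressWarnings(daily_decision(
            ev$tllr$model, run,
            rows[d, , drop = FALSE], prev, cfgd
          ))
          if (rep_d$qr_consulted) prev <- rep_d$pefr_tau_c
          day_reports[[as.character(rows$date[d])]] <- rep_d
        }
        reports[[id]] <- day_reports
      }
    }
  }
  out <- list(
    metrics = if (length(metrics_rows)) do.call(rbind, c(metrics_rows, make.row.names = FALSE)),
    qr_errors = if (length(qr_rows)) do.call(rbind, c(qr_rows, make.row.names = FALSE)),
    reports = reports,
    manifest = list(
      package_version = as.character(utils::packageVersion("pefrisk")),
      seed = seed, cohort_seed = cohort$config$seed,
      n_patients = length(cohort$patients), targets = targets,
      window = unclass(window)
    )
  )
  class(out) <- "pefr_run"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$metrics)) {
      utils::write.csv(out$metrics, file.path(out_dir, "metrics.csv"),
        row.names = FALSE
      )
    }
    if (!is.null(out$qr_errors)) {
      utils::write.csv(out$qr_errors, file.path(out_dir, "qr_errors.csv"),
        row.names = FALSE
      )
    }
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  out
}

#' @export
print.pefr_run <- function(x, ...) {
  cat("Pipeline run\n")
  if (!is.null(x$metrics)) {
    agg <- stats::aggregate(
      x$metrics[, c("sensitivity", "specificity")],
      by = list(method = x$metrics$method), FUN = mean
    )
    print(agg)
  }
  if (!is.null(x$qr_errors)) {
    cat(sprintf(
      "QR: mean Err_tau %.3f over %d patients\n",
      mean(x$qr_errors$err_tau), length(unique(x$qr_errors$patient_id))
    ))
  }
  invisible(x)
}
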