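# ---- preprocessing ---------------------------------------------------------

fit_scaler <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1 # constant columns map to 0
  list(mean = mu, sd = sd, cols = colnames(X))
}

apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)
  if (!is.null(scaler$cols)) X <- X[, scaler$cols, drop = FALSE]
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
}

feature_matrix <- function(rows, feature_cols) {
  missing_cols <- setdiff(feature_cols, names(rows))
  if (length(missing_cols)) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(rows[, feature_cols, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing entries in feature matrix; preprocess first")
  X
}

# stratified fold labels (1..k), balanced within each class
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

# stratified train/test split; test size = round(frac * n) per class
stratified_split <- function(y, test_frac = 0.2) {
  test <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_test <- round(test_frac * length(idx))
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

# ---- SMOTE -----------------------------------------------------------------

#' SMOTE minority oversampling
#'
#' Balances a binary dataset by synthesizing minority-class points as convex
#' combinations `x + u (x_nn - x)`, `u ~ Uniform(0, 1)`, of a minority point
#' and one of its `k_neighbors` nearest minority neighbours (Euclidean
#' distance in the feature space supplied -- standardize first). Original
#' rows are returned unchanged, followed by the synthetic rows; classes are
#' balanced to equal counts.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y binary labels (logical or 0/1); `TRUE`/1 need not be the
#'   minority.
#' @param k_neighbors number of nearest minority neighbours to draw from.
#' @param seed optional seed applied locally.
#' @return list with `x`, `y` and logical `synthetic` marking generated
#'   rows.
#' @export
smote_oversample <- function(x, y, k_neighbors = 5, seed = NULL) {
  x <- as.matrix(x)
  y <- as.logical(y)
  run <- function() {
    n1 <- sum(y)
    n0 <- sum(!y)
    if (n1 == n0) {
      return(list(x = x, y = y, synthetic = rep(FALSE, length(y))))
    }
    minority <- y == (n1 < n0)
    Xm <- x[minority, , drop = FALSE]
    nm <- nrow(Xm)
    if (nm < 2) stop("SMOTE needs at least 2 minority samples")
    k <- min(k_neighbors, nm - 1)
    if (k < 1) stop("k_neighbors must be >= 1")
    need <- abs(n0 - n1)
    D <- as.matrix(stats::dist(Xm))
    diag(D) <- Inf
    nn <- apply(D, 1, function(d) order(d)[seq_len(k)])
    nn <- matrix(nn, nrow = k) # k x nm
    base_i <- sample.int(nm, need, replace = TRUE)
    pick <- nn[cbind(sample.int(k, need, replace = TRUE), base_i)]
    u <- stats::runif(need)
    synth <- Xm[base_i, , drop = FALSE] +
      u * (Xm[pick, , drop = FALSE] - Xm[base_i, , drop = FALSE])
    list(
      x = rbind(x, synth),
      y = c(y, rep(n1 < n0, need)),
      synthetic = c(rep(FALSE, length(y)), rep(TRUE, need))
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# ---- source / target networks ---------------------------------------------

#' Train the population source network
#'
#' Fits the fully connected source model on data pooled from all patients
#' except the prediction target, under stratified k-fold cross-validation
#' (default 10-fold): k networks are trained (each with early stopping on
#' its validation fold's loss, SMOTE applied inside the training folds
#' only) and the one with the lowest validation loss is retained.
#'
#' @param pooled labeled daily feature rows from the non-target patients
#'   (needs `label` and the feature columns; `patient_id` recommended for
#'   the exclusion audit).
#' @param feature_cols predictor columns (default [pefr_feature_cols()]).
#' @param hidden hidden-layer widths.
#' @param k folds for cross-validation.
#' @param lr,batch,epochs,patience,l2 Adam/BCE training hyperparameters.
#' @param smote apply SMOTE inside training folds.
#' @param seed RNG seed (weights, folds, shuffles, SMOTE).
#' @return An object of class `source_model`: weights, scaler fitted on the
#'   pooled data, training metadata and loss curves per fold.
#' @export
train_source_model <- function(pooled, feature_cols = pefr_feature_cols(),
                               hidden = c(16, 8), k = 10, lr = 1e-3,
                               batch = 32, epochs = 200, patience = 20,
                               l2 = 1e-4, smote = TRUE, seed = 1) {
  y <- as.logical(pooled$label)
  if (length(unique(y)) < 2) stop("pooled labels contain a single class")
  if (!is.null(pooled$patient_id) && length(unique(pooled$patient_id)) < 2) {
    stop("pooled data spans a single patient; population pooling is empty")
  }
  feature_cols <- intersect(feature_cols, names(pooled))
  Xr <- feature_matrix(pooled, feature_cols)
  scaler <- fit_scaler(Xr)
  X <- apply_scaler(scaler, Xr)
  with_seed(seed, {
    fold <- stratified_folds(y, k)
    fits <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- fold != f
      Xtr <- X[tr, , drop = FALSE]
      ytr <- y[tr]
      if (smote) {
        sm <- smote_oversample(Xtr, ytr)
        Xtr <- sm$x
        ytr <- sm$y
      }
      init <- nn_init(ncol(X), hidden)
      fits[[f]] <- nn_train(init, Xtr, ytr, X[!tr, , drop = FALSE], y[!tr],
        lr = lr, batch = batch, epochs = epochs, patience = patience, l2 = l2
      )
    }
    best <- which.min(vapply(fits, `[[`, 0, "val_loss"))
    out <- list(
      weights = fits[[best]]$weights,
      scaler = scaler,
      feature_cols = feature_cols,
      hidden = hidden,
      val_loss = fits[[best]]$val_loss,
      best_fold = best,
      history = lapply(fits, function(f) {
        list(train = f$train_history, valid = f$val_history, epochs = f$epochs_run)
      }),
      patient_ids = unique(pooled$patient_id),
      hyper = list(
        k = k, lr = lr, batch = batch, epochs = epochs,
        patience = patience, l2 = l2, smote = smote, seed = seed
      )
    )
    class(out) <- "source_model"
    out
  })
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf(
    "Source network (%d-%d-%d-1) trained on %d patients; best of %d folds, val BCE %.4f\n",
    length(x$scaler$mean), x$hidden[1], x$hidden[2],
    length(x$patient_ids), x$hyper$k, x$val_loss
  ))
  invisible(x)
}

#' Fine-tune the source network on the target patient
#'
#' Retrains all layers of the source network on the target patient's
#' training rows at a reduced learning rate (default one tenth of the
#' source rate), under stratified k-fold cross-validation (default
#' 5-fold); the fold model with the best validation F1 is selected (ties
#' broken by validation loss). With `epochs = 0` the target model equals
#' the source model exactly.
#'
#' @param source a `source_model`.
#' @param target_train labeled feature rows of the target patient's
#'   training split.
#' @param k folds.
#' @param lr learning rate; default `0.1 *` the source rate.
#' @param epochs,patience,l2,batch training controls (defaults inherited
#'   from the source).
#' @param smote apply SMOTE inside training folds; if the target training
#'   labels are single-class an error instructs the caller accordingly.
#' @param freeze_first keep the first hidden layer at its source weights.
#' @param seed RNG seed.
#' @return An object of class `target_model` with the fine-tuned weights
#'   and a provenance link to the source.
#' @export
fine_tune_target <- function(source, target_train, k = 5, lr = NULL,
                             epochs = NULL, patience = NULL, l2 = NULL,
                             batch = NULL, smote = TRUE,
                             freeze_first = FALSE, seed = 1) {
  stopifnot(inherits(source, "source_model"))
  if (!nrow(target_train)) stop("empty target training data")
  y <- as.logical(target_train$label)
  if (length(unique(y)) < 2) {
    stop("target training labels are single-class; apply SMOTE-capable balancing after ensuring both classes are present")
  }
  h <- source$hyper
  if (is.null(lr)) lr <- 0.1 * h$lr
  if (is.null(epochs)) epochs <- h$epochs
  if (is.null(patience)) patience <- h$patience
  if (is.null(l2)) l2 <- h$l2
  if (is.null(batch)) batch <- h$batch
  X <- apply_scaler(source$scaler, feature_matrix(target_train, source$feature_cols))

  if (epochs == 0) {
    out <- list(
      weights = source$weights, source = source, val_f1 = NA_real_,
      val_loss = NA_real_, history = list(), epochs = 0L,
      hyper = list(k = k, lr = lr, epochs = 0L, seed = seed)
    )
    class(out) <- "target_model"
    return(out)
  }

  with_seed(seed, {
    fold <- stratified_folds(y, k)
    fits <- vector("list", k)
    f1s <- losses <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      Xtr <- X[tr, , drop = FALSE]
      ytr <- y[tr]
      if (smote) {
        sm <- smote_oversample(Xtr, ytr)
        Xtr <- sm$x
        ytr <- sm$y
      }
      fit <- nn_train(source$weights, Xtr, ytr,
        X[!tr, , drop = FALSE], y[!tr],
        lr = lr, batch = batch, epochs = epochs,
        patience = patience, l2 = l2, freeze_first = freeze_first
      )
      pv <- nn_prob(fit$weights, X[!tr, , drop = FALSE])
      mr <- compute_metrics(confusion_matrix(pv >= 0.5, y[!tr]))
      f1s[f] <- ifelse(is.na(mr$f1), 0, mr$f1)
      losses[f] <- fit$val_loss
      fits[[f]] <- fit
    }
    best <- order(-f1s, losses)[1]
    out <- list(
      weights = fits[[best]]$weights,
      source = source,
      val_f1 = f1s[best],
      val_loss = losses[best],
      best_fold = best,
      history = lapply(fits, function(f) {
        list(train = f$train_history, valid = f$val_history, epochs = f$epochs_run)
      }),
      epochs = fits[[best]]$epochs_run,
      hyper = list(
        k = k, lr = lr, epochs = epochs, patience = patience,
        l2 = l2, batch = batch, smote = smote,
        freeze_first = freeze_first, seed = seed
      )
    )
    class(out) <- "target_model"
    out
  })
}

#' @export
print.target_model <- function(x, ...) {
  cat(sprintf(
    "Target network fine-tuned from source (%d epochs run, val F1 %.3f)\n",
    x$epochs, x$val_f1
  ))
  invisible(x)
}

#' Last-hidden-layer activations
#'
#' Standardizes raw feature rows with the model's stored parameters and
#' returns the activations of the last hidden layer, the feature space the
#' logistic head is fitted on.
#'
#' @param model a `target_model` or `source_model`.
#' @param rows feature rows (data frame with the model's feature columns,
#'   or a numeric matrix already in column order).
#' @return numeric matrix, one row per input row, one column per unit of
#'   the last hidden layer.
#' @export
extract_features <- function(model, rows) {
  src <- if (inherits(model, "target_model")) model$source else model
  X <- if (is.data.frame(rows)) {
    feature_matrix(rows, src$feature_cols)
  } else {
    as.matrix(rows)
  }
  if (ncol(X) != length(src$scaler$mean)) {
    stop(sprintf(
      "feature dimension mismatch: got %d, expected %d",
      ncol(X), length(src$scaler$mean)
    ))
  }
  nn_hidden_act(model$weights, apply_scaler(src$scaler, X))
}

# ---- logistic head and classifier -----------------------------------------

#' Fit the logistic-regression head
#'
#' Ordinary maximum-likelihood logistic regression (IRLS via
#' [stats::glm.fit()]) of the binary risk label on the supplied features --
#' typically the last-hidden-layer activations of the target network.
#'
#' @param features numeric matrix (no intercept column; one is added).
#' @param labels binary labels.
#' @param threshold decision threshold on the predicted probability; class
#'   risk iff `p >= threshold` (ties go to the positive class).
#' @return An object of class `lr_head` with `coefficients` and
#'   `threshold`.
#' @export
fit_lr_head <- function(features, labels, threshold = 0.5) {
  X <- cbind(`(Intercept)` = 1, as.matrix(features))
  y <- as.numeric(as.logical(labels))
  if (length(unique(y)) < 2) stop("head training labels are single-class")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(), control = list(maxit = 100))
  )
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0 # aliased columns (e.g. dead ReLU units) drop out
  out <- list(
    coefficients = cf, threshold = threshold,
    converged = fit$converged
  )
  class(out) <- "lr_head"
  out
}

head_prob <- function(head, features) {
  z <- drop(cbind(1, as.matrix(features)) %*% head$coefficients)
  1 / (1 + exp(-z))
}

#' Assemble a transfer-learning classifier
#'
#' The prediction path is: standardize with the source scaler, forward
#' through the fine-tuned target network to its last hidden layer, then the
#' logistic head.
#'
#' @param target a `target_model`.
#' @param head an `lr_head` fitted on the target network's activations.
#' @return An object of class `tl_classifier`.
#' @export
tl_classifier <- function(target, head) {
  stopifnot(inherits(target, "target_model"), inherits(head, "lr_head"))
  structure(list(target = target, head = head), class = "tl_classifier")
}

#' @export
print.tl_classifier <- function(x, ...) {
  cat("Transfer-learning logistic classifier (TL + LR)\n")
  print(x$target)
  cat(sprintf(
    "Head: %d activation features, threshold %.2f\n",
    length(x$head$coefficients) - 1, x$head$threshold
  ))
  invisible(x)
}

#' Predict next-day risk
#'
#' @param clf a `tl_classifier` or `plain_lr`; a plain function
#'   `rows -> probability` is also accepted (scoring hook for custom
#'   models), with the default 0.5 threshold.
#' @param rows feature rows.
#' @return data frame with `probability` and logical `class_risk`
#'   (`TRUE` iff `p >= threshold`; the boundary goes to the risk class).
#' @export
predict_risk <- function(clf, rows) {
  if (is.function(clf)) {
    p <- clf(rows)
    return(data.frame(probability = p, class_risk = p >= 0.5))
  }
  p <- if (inherits(clf, "tl_classifier")) {
    head_prob(clf$head, extract_features(clf$target, rows))
  } else if (inherits(clf, "plain_lr")) {
    head_prob(clf$head, apply_scaler(clf$scaler, feature_matrix(rows, clf$feature_cols)))
  } else {
    stop("unsupported classifier")
  }
  thr <- clf$head$threshold
  data.frame(probability = p, class_risk = p >= thr)
}

#' @export
predict.tl_classifier <- function(object, newdata, ...) {
  predict_risk(object, newdata)
}

#' Stand-alone logistic-regression baseline
#'
#' Plain logistic regression on the standardized raw features (with SMOTE
#' balancing of the training rows), the baseline the transfer-learning
#' pipeline is compared against.
#'
#' @param train labeled feature rows.
#' @param feature_cols predictor columns.
#' @param smote balance training rows with SMOTE.
#' @param threshold decision threshold.
#' @param seed RNG seed (SMOTE draws).
#' @return An object of class `plain_lr`.
#' @export
fit_plain_lr <- function(train, feature_cols = pefr_feature_cols(),
                         smote = TRUE, threshold = 0.5, seed = 1) {
  feature_cols <- intersect(feature_cols, names(train))
  Xr <- feature_matrix(train, feature_cols)
  scaler <- fit_scaler(Xr)
  X <- apply_scaler(scaler, Xr)
  y <- as.logical(train$label)
  if (smote) {
    sm <- smote_oversample(X, y, seed = seed)
    X <- sm$x
    y <- sm$y
  }
  head <- fit_lr_head(X, y, threshold = threshold)
  structure(
    list(
      head = head, scaler = scaler, feature_cols = feature_cols,
      smote = smote
    ),
    class = "plain_lr"
  )
}

# ---- evaluation protocol ---------------------------------------------------

#' Evaluate a pipeline on one patient with the 80/20 protocol
#'
#' Splits the patient's labeled rows into stratified 80% train / 20% test,
#' trains the requested pipeline on the training split only (SMOTE and all
#' model selection confined to training folds), and computes test metrics
#' once on the untouched 20% -- to which no oversampling is applied.
#'
#' @param rows the target patient's labeled feature rows (>= 50 required).
#' @param pipeline `"lr"` or `"tllr"`.
#' @param seed RNG seed (split, folds, SMOTE, training).
#' @param source a `source_model` trained on the other patients; required
#'   for `"tllr"`.
#' @param feature_cols predictor columns.
#' @param chronological use the last 20% of days as the test set instead of
#'   a stratified random split.
#' @param ... passed to [fine_tune_target()].
#' @return list with `metrics` (a `metrics_report` including `roc_auc`),
#'   `cm`, `model`, `train_idx`, `test_idx`, `predictions`.
#' @export
evaluate_split <- function(rows, pipeline = c("lr", "tllr"), seed = 1,
                           source = NULL, feature_cols = pefr_feature_cols(),
                           chronological = FALSE, ...) {
  pipeline <- match.arg(pipeline)
  if (nrow(rows) < 50) stop("need at least 50 labeled rows")
  y <- as.logical(rows$label)
  if (length(unique(y)) < 2) stop("labels are single-class")
  test_idx <- with_seed(seed, {
    if (chronological) {
      seq.int(nrow(rows) - round(0.2 * nrow(rows)) + 1, nrow(rows))
    } else {
      stratified_split(y, 0.2)
    }
  })
  train_idx <- setdiff(seq_len(nrow(rows)), test_idx)
  train <- rows[train_idx, , drop = FALSE]
  test <- rows[test_idx, , drop = FALSE]

  if (pipeline == "lr") {
    model <- fit_plain_lr(train, feature_cols, seed = seed)
  } else {
    if (is.null(source)) stop("'source' model required for the TL pipeline")
    target <- fine_tune_target(source, train, seed = seed, ...)
    feats <- extract_features(target, train)
    sm <- with_seed(seed + 1, smote_oversample(feats, train$label))
    head <- fit_lr_head(sm$x, sm$y)
    model <- tl_classifier(target, head)
  }
  pred <- predict_risk(model, test)
  cm <- confusion_matrix(pred$class_risk, test$label)
  metrics <- compute_metrics(cm)
  metrics$roc_auc <- suppressWarnings(roc_auc(pred$probability, test$label))
  list(
    metrics = metrics, cm = cm, model = model,
    train_idx = train_idx, test_idx = test_idx, predictions = pred
  )
}

#' Leave-one-patient-out evaluation of LR vs TL + LR
#'
#' For a target patient: trains the source network on all other patients'
#' rows, then evaluates both the stand-alone LR baseline and the TL + LR
#' pipeline on the target's 80/20 split with a shared seed.
#'
#' @param features labeled cohort feature table (multiple patients).
#' @param target_id patient to predict.
#' @param seed RNG seed.
#' @param methods subset of `c("lr", "tllr")`.
#' @param source optional pre-trained `source_model` (must exclude the
#'   target).
#' @param source_args list of extra arguments for [train_source_model()].
#' @param ... passed to [evaluate_split()].
#' @return named list of [evaluate_split()] results (plus the source).
#' @export
evaluate_patient <- function(features, target_id, seed = 1,
                             methods = c("lr", "tllr"), source = NULL,
                             source_args = list(), ...) {
  rows <- features[features$patient_id == target_id, , drop = FALSE]
  if (!nrow(rows)) stop("unknown target patient: ", target_id)
  out <- list()
  if ("tllr" %in% methods && is.null(source)) {
    pooled <- features[features$patient_id != target_id, , drop = FALSE]
    source <- do.call(
      train_source_model,
      c(list(pooled = pooled, seed = seed), source_args)
    )
  }
  if (!is.null(source) && target_id %in% source$patient_ids) {
    stop("source model was trained on the target patient")
  }
  for (m in methods) {
    out[[m]] <- evaluate_split(rows,
      pipeline = m, seed = seed,
      source = if (m == "tllr") source else NULL, ...
    )
  }
  out$source <- source
  out
}
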