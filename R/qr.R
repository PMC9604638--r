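#' Pinball (check) loss
#'
#' `rho_tau(u) = u * (tau - 1\{u < 0\})`, the loss whose minimizer over a
#' constant is the empirical tau-quantile.
#'
#' @param u numeric residuals.
#' @param tau quantile level in (0, 1).
#' @return Sum of the check loss over `u`.
#' @export
pinball_loss <- function(u, tau) {
  sum(u * (tau - (u < 0)))
}

#' Linear quantile regression by exact basis pivoting
#'
#' Minimizes the pinball loss `sum(rho_tau(y - X beta))`. The optimum of
#' this piecewise-linear program is attained at a vertex interpolating p
#' observations exactly; the solver starts from a least-squares fit, selects
#' an initial full-rank basis of the p smallest-residual rows, and pivots
#' (exchanging one basis observation at a time via an exact breakpoint line
#' search) until the one-sided directional derivatives certify optimality.
#' When the optimal set is a flat face, the returned vertex is one of its
#' corners (which corner depends on the pivot path).
#'
#' @param x design matrix (include the intercept column yourself, or use
#'   the default of [sliding_window_run()] which adds one). A vector is
#'   treated as a single column.
#' @param y numeric response.
#' @param tau quantile level in (0, 1).
#' @param tol numerical tolerance for optimality certification.
#' @param max_pivots pivot cap (degeneracy guard).
#' @return An object of class `pinball_fit`: list with `coefficients`,
#'   `tau`, `loss`, `fitted`, `residuals`, `basis` (row indices interpolated
#'   exactly), `pivots`, `converged`.
#' @export
fit_qr <- function(x, y, tau, tol = 1e-9, max_pivots = NULL) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.double(y)
  n <- nrow(X)
  p <- ncol(X)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1) {
    stop("'tau' must be a single value in (0, 1)")
  }
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (n < p + 2) stop(sprintf("need at least %d rows for %d predictors", p + 2, p))
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    if (is.null(bad)) bad <- as.character(qrX$pivot[(qrX$rank + 1):p])
    stop(
      "design matrix is rank deficient; collinear columns: ",
      paste(bad, collapse = ", ")
    )
  }
  if (is.null(max_pivots)) max_pivots <- 20L * n + 200L

  # initial basis: smallest |LS residual| rows that keep X_B full rank
  r0 <- stats::lm.fit(X, y)$residuals
  ord <- order(abs(r0))
  basis <- integer(0)
  for (i in ord) {
    cand <- c(basis, i)
    if (qr(X[cand, , drop = FALSE])$rank == length(cand)) basis <- cand
    if (length(basis) == p) break
  }
  beta <- drop(solve(X[basis, , drop = FALSE], y[basis]))
  loss <- pinball_loss(y - drop(X %*% beta), tau)
  scale0 <- max(1, mean(abs(y)))

  pivots <- 0L
  converged <- FALSE
  stalls <- 0L
  while (pivots < max_pivots) {
    r <- drop(y - X %*% beta)
    r[basis] <- 0
    is_basis <- logical(n)
    is_basis[basis] <- TRUE
    XBinv <- solve(X[basis, , drop = FALSE])
    H <- X %*% XBinv # H[i, k] = x_i' delta_k, with X_B delta_k = e_k
    nb <- which(!is_basis)
    zr <- nb[abs(r[nb]) <= tol * scale0] # degenerate zero-residual rows
    nz <- setdiff(nb, zr)

    w0 <- tau - (r < 0) # subgradient weight away from kinks
    g0 <- if (length(nz)) {
      colSums(H[nz, , drop = FALSE] * w0[nz])
    } else {
      numeric(p)
    }
    if (length(zr)) {
      Hz <- H[zr, , drop = FALSE]
      # at a kink the effective weight depends on the movement direction
      d_plus <- (1 - tau) - g0 - colSums(Hz * tau) + colSums(pmax(Hz, 0))
      d_minus <- -tau - g0 - colSums(Hz * tau) + colSums(pmin(Hz, 0))
    } else {
      d_plus <- (1 - tau) - g0
      d_minus <- -tau - g0
    }

    viol <- pmax(-d_plus, d_minus)
    k <- which.max(viol)
    if (viol[k] <= tol) {
      converged <- TRUE
      break
    }
    sigma <- if (-d_plus[k] >= d_minus[k]) 1 else -1
    s0 <- if (sigma == 1) d_plus[k] else -d_minus[k]

    h <- sigma * H[, k]
    cand <- nz[abs(h[nz]) > tol]
    tt <- r[cand] / h[cand]
    keep <- tt > tol
    cand <- cand[keep]
    tt <- tt[keep]
    if (!length(cand)) break # flat/unbounded direction: stop at current vertex
    o <- order(tt)
    cand <- cand[o]
    tt <- tt[o]
    slope <- s0 + cumsum(abs(h[cand]))
    enter_pos <- which(slope >= -tol)[1]
    if (is.na(enter_pos)) break
    enter <- cand[enter_pos]

    basis[k] <- enter
    beta <- drop(solve(X[basis, , drop = FALSE], y[basis]))
    new_loss <- pinball_loss(y - drop(X %*% beta), tau)
    if (new_loss > loss + tol * scale0) break # numerical safety
    stalls <- if (new_loss > loss - tol * scale0) stalls + 1L else 0L
    loss <- new_loss
    pivots <- pivots + 1L
    if (stalls > 2L * p + 10L) break # cycling guard on degenerate faces
  }

  fitted <- drop(X %*% beta)
  names(beta) <- colnames(X)
  out <- list(
    coefficients = beta, tau = tau, loss = pinball_loss(y - fitted, tau),
    fitted = fitted, residuals = y - fitted, basis = sort(basis),
    pivots = pivots, converged = converged
  )
  class(out) <- "pinball_fit"
  out
}

#' @export
print.pinball_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Quantile regression fit (tau = %.2f, pinball loss %.4g, %d pivots)\n",
    x$tau, x$loss, x$pivots
  ))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.pinball_fit <- function(object, ...) object$coefficients

#' @export
residuals.pinball_fit <- function(object, ...) object$residuals

#' Sliding-window specification
#'
#' The variable sliding-window protocol fits the quantile model on `train`
#' consecutive days, validates it on the next `valid` days (window size
#' `W = train + valid`), then uses the model for the following `m` days
#' before sliding forward by `m` and refitting.
#'
#' @param train days in the training block (D_train).
#' @param valid days in the validation block (D_valid); default half of
#'   `train` (the 2:1 ratio of the reference configuration, e.g. 30/15).
#' @param m model-usage / slide length in days.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(train = 30, valid = round(train / 2), m = 7) {
  train <- as.integer(train)
  valid <- as.integer(valid)
  m <- as.integer(m)
  W <- train + valid
  if (train < 3) stop("'train' too small")
  if (valid < 0) stop("'valid' must be >= 0")
  if (m < 1 || m > W) stop("'m' must be in [1, W]")
  structure(list(W = W, train = train, valid = valid, m = m),
    class = "window_spec"
  )
}

#' Default quantile grid
#'
#' `\{0.01, 0.05, 0.10, ..., 0.95, 0.99\}`, banded by [tau_bands()] into ten
#' ranges of width 0.1 for reporting.
#' @return numeric vector of quantile levels.
#' @export
default_tau_grid <- function() {
  sort(unique(c(0.01, seq(0.05, 0.95, by = 0.05), 0.99)))
}

#' Tau reporting bands
#' @return data frame with band `label`, `lo`, `hi` (inclusive bounds).
#' @export
tau_bands <- function() {
  lo <- c(0.01, seq(0.11, 0.91, by = 0.10))
  hi <- c(seq(0.10, 0.90, by = 0.10), 0.99)
  data.frame(
    label = sprintf("%.2f-%.2f", lo, hi),
    lo = lo, hi = hi, stringsAsFactors = FALSE
  )
}

#' Default predictor columns of a daily feature row
#' @return character vector of column names.
#' @export
pefr_feature_cols <- function() {
  c(
    "pm25_dose", "co2_mean", "temp_mean", "rh_mean",
    "yesterday_am_pefr", "yesterday_pm_pefr",
    "age", "sex", "bmi", "cooking_level", "road_level", "income_level"
  )
}

qr_design <- function(series, predictors) {
  X <- cbind(`(Intercept)` = 1, as.matrix(series[, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  # per-patient series make patient-level covariates constant; drop them
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) {
    stats::sd(v) > 1e-12
  }))
  X[, keep, drop = FALSE]
}

#' Fit quantile models under the variable sliding-window protocol
#'
#' At iteration k the model is trained on days `[s_k, s_k + train)`,
#' validated on the next `valid` days, and used to predict the following
#' `min(m, days remaining)` days; the window then slides forward by `m`
#' days. Every day after the first window is predicted exactly once, and no
#' prediction uses same-day or future data.
#'
#' @param series data frame of daily feature rows ordered by date, with the
#'   response column present.
#' @param window a [window_spec()].
#' @param taus quantile levels to fit (default [default_tau_grid()]).
#' @param predictors character vector of predictor columns; default: the
#'   columns of [pefr_feature_cols()] present in `series`.
#' @param response response column name (default `"am_pefr"`).
#' @return An object of class `sliding_qr`: list with `iterations` (per-k
#'   coefficient matrices and diagnostics), `predictions` (data frame with
#'   one row per predicted day and one column per tau), `taus`, `window`,
#'   `response`, `predictors`.
#' @export
sliding_window_run <- function(series, window = window_spec(),
                               taus = default_tau_grid(),
                               predictors = NULL, response = "am_pefr") {
  stopifnot(inherits(window, "window_spec"))
  n <- nrow(series)
  if (n <= window$W) {
    stop(sprintf("series length (%d) must exceed window size W = %d", n, window$W))
  }
  if (is.null(predictors)) {
    predictors <- intersect(pefr_feature_cols(), names(series))
  }
  missing_cols <- setdiff(c(predictors, response), names(series))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  y <- series[[response]]
  X <- qr_design(series, predictors)

  iterations <- list()
  pred_rows <- list()
  s <- 1L
  k <- 0L
  while (s + window$W - 1L < n) {
    k <- k + 1L
    tr <- s:(s + window$train - 1L)
    va <- if (window$valid > 0) {
      (s + window$train):(s + window$W - 1L)
    } else {
      integer(0)
    }
    first_pred <- s + window$W
    last_pred <- min(n, s + window$W + window$m - 1L)
    pr <- first_pred:last_pred

    coefs <- matrix(NA_real_, ncol(X), length(taus),
      dimnames = list(colnames(X), sprintf("%g", taus))
    )
    train_loss <- valid_loss <- numeric(length(taus))
    for (j in seq_along(taus)) {
      fit <- fit_qr(X[tr, , drop = FALSE], y[tr], taus[j])
      coefs[, j] <- fit$coefficients
      train_loss[j] <- fit$loss / length(tr)
      valid_loss[j] <- if (length(va)) {
        pinball_loss(y[va] - drop(X[va, , drop = FALSE] %*% coefs[, j]), taus[j]) /
          length(va)
      } else {
        NA_real_
      }
    }
    P <- X[pr, , drop = FALSE] %*% coefs
    pred_rows[[k]] <- data.frame(
      day = pr, iteration = k,
      observed = y[pr],
      P, check.names = FALSE
    )
    iterations[[k]] <- list(
      k = k, train = range(tr), valid = if (length(va)) range(va) else NULL,
      predict = range(pr), coefficients = coefs,
      train_loss = train_loss, valid_loss = valid_loss
    )
    s <- s + window$m
  }
  predictions <- do.call(rbind, pred_rows)
  names(predictions)[-(1:3)] <- sprintf("%g", taus)
  crossings <- sum(apply(
    as.matrix(predictions[, -(1:3), drop = FALSE]), 1,
    function(v) any(diff(v) < 0)
  ))
  out <- list(
    iterations = iterations, predictions = predictions, taus = taus,
    window = window, response = response,
    predictors = setdiff(colnames(X), "(Intercept)"),
    n_crossing_days = crossings
  )
  class(out) <- "sliding_qr"
  out
}

#' @export
print.sliding_qr <- function(x, ...) {
  w <- x$window
  cat(sprintf(
    "Sliding-window quantile regression: W = %d (%d train / %d valid), m = %d\n",
    w$W, w$train, w$valid, w$m
  ))
  cat(sprintf(
    "%d iterations, %d predicted days, %d tau levels; %d days with quantile crossing\n",
    length(x$iterations), nrow(x$predictions), length(x$taus),
    x$n_crossing_days
  ))
  invisible(x)
}

#' @export
summary.sliding_qr <- function(object, ...) {
  errs <- vapply(object$taus, function(tau) {
    col <- sprintf("%g", tau)
    err_tau(object$predictions[[col]], object$predictions$observed, tau)
  }, 0)
  data.frame(tau = object$taus, err_tau = errs)
}

#' Predict a conditional PEFR quantile
#'
#' Uses the most recent iteration's coefficients (the model currently "in
#' use" under the sliding protocol). Crossing of the requested quantile by
#' lower quantiles at `x` is detected and flagged via the
#' `"crossed"` attribute.
#'
#' @param model a `sliding_qr` object (or a single iteration's coefficient
#'   matrix with a `taus` attribute).
#' @param x named numeric vector (or one-row data frame) of predictor
#'   values; the intercept is added automatically.
#' @param tau quantile level; must be on the fitted grid.
#' @param iteration which iteration's model to use (default: last).
#' @return predicted quantile of the response (L/min for PEFR), with
#'   attribute `crossed` (logical).
#' @export
predict_quantile <- function(model, x, tau, iteration = NULL) {
  stopifnot(inherits(model, "sliding_qr"))
  j <- match(TRUE, abs(model$taus - tau) < 1e-12)
  if (is.na(j)) {
    stop(
      "tau not on the fitted grid; available: ",
      paste(sprintf("%g", model$taus), collapse = ", ")
    )
  }
  if (is.null(iteration)) iteration <- length(model$iterations)
  coefs <- model$iterations[[iteration]]$coefficients
  xv <- qr_predict_row(coefs, x)
  all_q <- drop(xv %*% coefs)
  pred <- all_q[j]
  crossed <- any(diff(all_q) < 0)
  structure(unname(pred), crossed = crossed)
}

qr_predict_row <- function(coefs, x) {
  if (is.data.frame(x)) x <- unlist(x[1, , drop = TRUE])
  vars <- setdiff(rownames(coefs), "(Intercept)")
  missing_vars <- setdiff(vars, names(x))
  if (length(missing_vars)) {
    stop("missing predictor values: ", paste(missing_vars, collapse = ", "))
  }
  matrix(c(1, as.numeric(x[vars])), 1,
    dimnames = list(NULL, c("(Intercept)", vars))
  )
}

#' Quantile calibration error Err_tau
#'
#' `Err_tau = |N_tau / N - tau|`, where `N_tau` counts test days whose
#' observed value falls strictly under that day's predicted tau-quantile
#' (ties count as not-under; the response is continuous so ties have
#' measure zero).
#'
#' @param predicted per-day predicted tau-quantiles.
#' @param observed per-day observed responses, aligned with `predicted`.
#' @param tau the quantile level.
#' @return the calibration error, in `[0, max(tau, 1 - tau)]`.
#' @export
err_tau <- function(predicted, observed, tau) {
  keep <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[keep]
  observed <- observed[keep]
  n <- length(predicted)
  if (n < 1) stop("err_tau needs at least one aligned (prediction, observation) pair")
  if (length(observed) != n) stop("prediction/observation length mismatch")
  abs(sum(observed < predicted) / n - tau)
}

#' Grid search over sliding-window configurations
#'
#' Runs the sliding-window protocol for every combination of training size
#' and slide length, pools the predicted days, and reports the mean Err_tau
#' per tau band (rows) and training size (columns), for each slide length.
#' The best pairing minimizes the band-averaged error.
#'
#' @param series daily feature rows (see [sliding_window_run()]).
#' @param train_sizes training-block sizes to try (days).
#' @param m_set slide lengths to try (days).
#' @param taus quantile grid.
#' @param predictors,response passed to [sliding_window_run()].
#' @param valid_ratio validation block size as a fraction of the training
#'   block (default 0.5, the 2:1 train:valid ratio).
#' @return list with `tables` (one band-by-train matrix per m), `best`
#'   (list with `train`, `m`, `mean_err`), and `summary` (long data frame).
#' @export
grid_search_windows <- function(series, train_sizes = c(30, 35, 45, 50),
                                m_set = 7, taus = default_tau_grid(),
                                predictors = NULL, response = "am_pefr",
                                valid_ratio = 0.5) {
  if (!length(train_sizes) || !length(m_set)) {
    stop("'train_sizes' and 'm_set' must be non-empty")
  }
  bands <- tau_bands()
  band_of <- function(tau) which(tau >= bands$lo - 1e-9 & tau <= bands$hi + 1e-9)[1]
  tau_band <- vapply(taus, band_of, 0L)

  tables <- list()
  rows <- list()
  best <- list(mean_err = Inf)
  for (m in m_set) {
    tab <- matrix(NA_real_, nrow(bands), length(train_sizes),
      dimnames = list(bands$label, as.character(train_sizes))
    )
    for (ti in seq_along(train_sizes)) {
      tr <- train_sizes[ti]
      w <- window_spec(train = tr, valid = round(tr * valid_ratio), m = m)
      if (nrow(series) <= w$W) {
        stop(sprintf(
          "series length %d too short for window W = %d", nrow(series), w$W
        ))
      }
      run <- sliding_window_run(series, w,
        taus = taus,
        predictors = predictors, response = response
      )
      errs <- summary(run)$err_tau
      tab[, ti] <- vapply(seq_len(nrow(bands)), function(b) {
        if (any(tau_band == b)) mean(errs[tau_band == b]) else NA_real_
      }, 0)
      me <- mean(tab[, ti], na.rm = TRUE) # bands without grid points drop out
      rows[[length(rows) + 1]] <- data.frame(
        train = tr, m = m, mean_err = me
      )
      if (me < best$mean_err) best <- list(train = tr, m = m, mean_err = me)
    }
    tables[[as.character(m)]] <- tab
  }
  list(tables = tables, best = best, summary = do.call(rbind, rows))
}

#' Marginal averages of a band-by-window error table
#'
#' Appends the per-column average row and per-band average column, and
#' computes the grand average. Published summaries of such tables are
#' typically reported at a fixed display precision, and their grand average
#' is then the mean of the rounded band averages; pass `digits` to
#' reproduce that convention (e.g. `digits = 3` for a 3-decimal table),
#' or leave `NULL` for raw arithmetic.
#'
#' @param cells numeric band-by-window matrix of mean Err_tau values.
#' @param digits optional rounding applied to the band averages before the
#'   grand average is taken.
#' @return list with `table` (the input with an average row and column
#'   appended), `col_avg`, `band_avg`, `grand`.
#' @export
summarize_err_table <- function(cells, digits = NULL) {
  cells <- as.matrix(cells)
  col_avg <- colMeans(cells)
  band_avg <- rowMeans(cells)
  shown_band <- if (is.null(digits)) band_avg else round(band_avg, digits)
  grand <- mean(shown_band)
  tab <- rbind(
    cbind(cells, average = band_avg),
    average = c(col_avg, grand)
  )
  list(table = tab, col_avg = col_avg, band_avg = band_avg, grand = grand)
}
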