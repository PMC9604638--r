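test_that("quantile fits solve canonical problems exactly", {
  f <- fit_qr(matrix(1, 3, 1), c(1, 2, 3), 0.5)
  expect_equal(unname(f$coefficients), 2)
  expect_true(f$converged)

  x <- cbind(1, seq_len(20))
  for (tau in c(0.2, 0.5, 0.8)) {
    f <- fit_qr(x, 3 + 2 * seq_len(20), tau)
    expect_equal(unname(f$coefficients), c(3, 2), tolerance = 1e-10)
  }
})

test_that("flat-optimum fits attain the brute-force grid minimum loss", {
  y <- as.numeric(1:10)
  for (tau in c(0.1, 0.5, 0.9)) {
    f <- fit_qr(matrix(1, 10, 1), y, tau)
    grid_min <- min(vapply(
      seq(0, 11, by = 0.001),
      function(b) pinball_loss(y - b, tau), 0
    ))
    expect_equal(f$loss, grid_min, tolerance = 1e-9)
  }
})

test_that("quantile fits recover linear conditional quantiles", {
  set.seed(14)
  n <- 5000
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n)
  f <- fit_qr(cbind(1, x), y, 0.5)
  expect_lt(max(abs(f$coefficients - c(1, 2))), 0.1)
  # a non-central quantile shifts only the intercept
  f9 <- fit_qr(cbind(1, x), y, 0.9)
  expect_lt(abs(f9$coefficients[1] - (1 + qnorm(0.9))), 0.1)
  expect_lt(abs(f9$coefficients[2] - 2), 0.1)
})

test_that("fit errors are informative", {
  expect_error(fit_qr(cbind(1, 1:10), 1:10, 1.5), "tau")
  expect_error(fit_qr(cbind(1, 1:10), 1:10, 0), "tau")
  X <- cbind(a = rnorm(20), b = rnorm(20))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fit_qr(X, rnorm(20), 0.5), "collinear.*c")
  expect_error(fit_qr(cbind(1, rnorm(3), rnorm(3)), rnorm(3), 0.5), "at least")
})

test_that("fitted loss never exceeds the empirical-quantile baseline and is calibrated in-sample", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(40:120, 1)
    p <- sample(1:4, 1)
    X <- cbind(1, matrix(rnorm(n * p), n, p))
    y <- X %*% runif(p + 1, -2, 2) + rnorm(n)
    tau <- runif(1, 0.1, 0.9)
    f <- fit_qr(X, y, tau)
    base <- pinball_loss(y - quantile(y, tau, type = 7), tau)
    expect_lte(f$loss, base + 1e-8)
    frac_neg <- mean(f$residuals < 0)
    expect_gte(frac_neg, tau - (p + 2) / n)
    expect_lte(frac_neg, tau + (p + 2) / n)
  }
})

test_that("sliding windows partition the series into train/valid/predict blocks", {
  feats <- small_features()
  rows <- feats[feats$patient_id == feats$patient_id[1], ][1:60, ]
  w <- window_spec(train = 30, valid = 15, m = 7)
  expect_equal(w$W, 45)
  run <- sliding_window_run(rows, w, taus = c(0.2, 0.5, 0.8))
  expect_equal(length(run$iterations), 3)
  expect_equal(nrow(run$predictions), 15) # 60 - 45, in blocks of 7, 7, 1
  expect_equal(as.numeric(table(run$predictions$iteration)), c(7, 7, 1))
  # predictions never use same-day or future data
  for (it in run$iterations) {
    expect_lt(it$train[2], it$predict[1])
    expect_lt(it$valid[2], it$predict[1])
  }
  # every post-window day predicted exactly once
  expect_equal(run$predictions$day, 46:60)

  one <- sliding_window_run(rows, window_spec(30, 15, m = 1), taus = 0.5)
  expect_equal(length(one$iterations), 60 - 45)
  expect_error(
    sliding_window_run(rows[1:45, ], w, taus = 0.5),
    "must exceed window size"
  )
})

test_that("quantile predictions are dot products with crossing detection", {
  feats <- small_features()
  rows <- feats[feats$patient_id == feats$patient_id[1], ][1:60, ]
  run <- sliding_window_run(rows, window_spec(30, 15, 7), taus = c(0.2, 0.5, 0.8))
  x <- rows[55, ]
  q <- predict_quantile(run, x, 0.5)
  cf <- run$iterations[[3]]$coefficients[, "0.5"]
  manual <- cf[1] + sum(cf[-1] * unlist(x[names(cf)[-1]]))
  expect_equal(as.numeric(q), unname(manual))
  expect_type(attr(q, "crossed"), "logical")
  expect_error(predict_quantile(run, x, 0.33), "available")
})

test_that("Err_tau is the absolute coverage gap with strict ties-out counting", {
  expect_equal(err_tau(rep(10, 100), c(rep(5, 20), rep(15, 80)), 0.2), 0)
  expect_equal(err_tau(rep(10, 50), rep(20, 50), 0.2), 0.2) # N_tau = 0
  expect_equal(err_tau(rep(10, 7), c(5, 6, 11, 12, 13, 14, 15), 0.2), abs(2 / 7 - 0.2))
  expect_equal(err_tau(rep(10, 5), rep(10, 5), 0.3), 0.3) # ties are not under
  expect_error(err_tau(numeric(0), numeric(0), 0.5), "at least one")
  set.seed(2)
  for (i in 1:50) {
    tau <- runif(1, 0.01, 0.99)
    e <- err_tau(rnorm(30), rnorm(30), tau)
    expect_gte(e, 0)
    expect_lte(e, max(tau, 1 - tau))
  }
})

test_that("window grid search reports banded errors and a minimizer", {
  feats <- small_features()
  rows <- feats[feats$patient_id == feats$patient_id[2], ]
  gs <- grid_search_windows(rows,
    train_sizes = 30, m_set = 7,
    taus = c(0.05, 0.5, 0.95)
  )
  expect_equal(ncol(gs$tables[["7"]]), 1)
  expect_equal(gs$best$train, 30)
  expect_equal(gs$best$m, 7)
  expect_error(grid_search_windows(rows, integer(0), 7), "non-empty")
})

test_that("marginal averages of the error table follow the reporting convention", {
  cells <- matrix(1:12 / 100, 3, 4)
  s <- summarize_err_table(cells)
  expect_equal(s$col_avg, colMeans(cells))
  expect_equal(s$band_avg, rowMeans(cells))
  expect_equal(s$grand, mean(rowMeans(cells)))
  expect_equal(dim(s$table), c(4, 5))
  s3 <- summarize_err_table(cells, digits = 3)
  expect_equal(s3$grand, mean(round(rowMeans(cells), 3)))
})
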