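# fast hyperparameters for structural tests (protocol-scale settings are
# exercised in the acceptance suite)
fast_src <- list(k = 3, epochs = 40, patience = 10)

test_that("SMOTE balances classes with convex minority interpolation", {
  set.seed(21)
  X <- matrix(rnorm(200), 100, 2)
  y <- rep(c(TRUE, FALSE), 50)
  out <- smote_oversample(X, y)
  expect_identical(out$x, X) # already balanced: unchanged
  expect_false(any(out$synthetic))

  X1 <- matrix(c(0, 1, rnorm(8, 10)), ncol = 1)
  y1 <- c(TRUE, TRUE, rep(FALSE, 8))
  out1 <- smote_oversample(X1, y1, k_neighbors = 1, seed = 4)
  synth <- out1$x[out1$synthetic, 1]
  expect_true(all(synth >= 0 & synth <= 1)) # convex hull of {0, 1}
  expect_equal(sum(out1$y), sum(!out1$y))

  X2 <- matrix(rnorm(100 * 3), 100, 3)
  y2 <- c(rep(TRUE, 20), rep(FALSE, 80))
  out2 <- smote_oversample(X2, y2, seed = 9)
  expect_equal(sum(out2$y), 80)
  expect_equal(sum(!out2$y), 80)
  expect_identical(out2$x[1:100, ], X2) # originals untouched

  expect_error(smote_oversample(matrix(1:10, ncol = 1), c(TRUE, rep(FALSE, 9))),
    "at least 2"
  )
})

test_that("source training is seeded-deterministic and excludes the target", {
  feats <- small_features()
  pooled <- feats[feats$patient_id != "P01", ]
  s1 <- do.call(train_source_model, c(list(pooled, seed = 3), fast_src))
  s2 <- do.call(train_source_model, c(list(pooled, seed = 3), fast_src))
  expect_identical(s1$weights, s2$weights)
  expect_false("P01" %in% s1$patient_ids)
  expect_error(
    evaluate_patient(feats, "P02", source = s1),
    "trained on the target"
  )
  one_class <- pooled
  one_class$label <- FALSE
  expect_error(train_source_model(one_class), "single class")
})

test_that("the network separates linearly separable pooled data", {
  set.seed(6)
  n <- 300
  df <- data.frame(
    patient_id = rep(c("A", "B"), each = n / 2),
    f1 = rnorm(n), f2 = rnorm(n)
  )
  df$label <- df$f1 > 0
  src <- train_source_model(df,
    feature_cols = c("f1", "f2"), k = 3,
    epochs = 120, patience = 30, seed = 2
  )
  X <- apply_scaler(src$scaler, as.matrix(df[, c("f1", "f2")]))
  acc <- mean((nn_prob(src$weights, X) >= 0.5) == df$label)
  expect_gte(acc, 0.95)
})

test_that("zero fine-tuning epochs reproduce the source exactly", {
  feats <- small_features()
  pooled <- feats[feats$patient_id != "P01", ]
  rows <- feats[feats$patient_id == "P01", ]
  src <- do.call(train_source_model, c(list(pooled, seed = 3), fast_src))
  tgt0 <- fine_tune_target(src, rows, epochs = 0)
  expect_identical(tgt0$weights, src$weights)
  # and the TL+LR prediction path then equals source-features LR exactly
  f_t <- extract_features(tgt0, rows)
  f_s <- extract_features(src, rows)
  expect_identical(f_t, f_s)
})

test_that("fine-tuning usually improves the source's fit on the target patient", {
  feats <- small_features()
  wins <- 0
  for (s in 1:5) {
    id <- sprintf("P%02d", (s %% 4) + 1)
    pooled <- feats[feats$patient_id != id, ]
    rows <- feats[feats$patient_id == id, ]
    src <- do.call(train_source_model, c(list(pooled, seed = s), fast_src))
    tgt <- fine_tune_target(src, rows, seed = s, epochs = 80, patience = 15)
    X <- apply_scaler(src$scaler, as.matrix(rows[, src$feature_cols]))
    if (nn_bce(nn_prob(tgt$weights, X), rows$label) <=
      nn_bce(nn_prob(src$weights, X), rows$label)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 4)
})

test_that("fine-tuning on shuffled labels has chance-level balanced accuracy", {
  feats <- small_features()
  rows <- feats[feats$patient_id == "P02", ]
  rows$label <- with_seed(17, sample(rows$label))
  pooled <- feats[feats$patient_id != "P02", ]
  src <- do.call(train_source_model, c(list(pooled, seed = 5), fast_src))
  ev <- evaluate_split(rows, "tllr", seed = 5, source = src)
  wacc <- ev$metrics$weighted_accuracy
  expect_gte(wacc, 0.3)
  expect_lte(wacc, 0.7)
})

test_that("last-hidden-layer features have the documented geometry", {
  feats <- small_features()
  pooled <- feats[feats$patient_id != "P03", ]
  src <- do.call(train_source_model, c(list(pooled, seed = 8), fast_src))
  A <- extract_features(src, pooled[1:20, ])
  expect_equal(dim(A), c(20, 8)) # last hidden layer width
  expect_true(all(A >= 0)) # ReLU activations
  same <- extract_features(src, pooled[c(1, 1), ])
  expect_identical(same[1, ], same[2, ])
  expect_error(extract_features(src, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("the logistic head matches an independent Newton-IRLS oracle", {
  set.seed(33)
  X <- matrix(rnorm(40), 20, 2)
  y <- rbinom(20, 1, plogis(0.5 + X %*% c(1, -1)))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  head <- fit_lr_head(X, y)

  # independent oracle: hand-rolled Newton-Raphson on the log-likelihood
  b <- rep(0, 3)
  Xi <- cbind(1, X)
  for (it in 1:50) {
    p <- plogis(drop(Xi %*% b))
    W <- p * (1 - p)
    b <- b + solve(t(Xi) %*% (Xi * W), t(Xi) %*% (y - p))
  }
  expect_lt(max(abs(head$coefficients - b)), 1e-6)

  expect_error(fit_lr_head(X, rep(1, 20)), "single-class")
})

test_that("risk classification puts the 0.5 boundary in the risk class", {
  set.seed(1)
  X <- matrix(c(rnorm(30, -2), rnorm(30, 2)), ncol = 1)
  y <- rep(c(FALSE, TRUE), each = 30)
  head <- fit_lr_head(X, y)
  p_new <- head_prob(head, matrix(c(-3, 3), ncol = 1))
  expect_equal(p_new >= 0.5, c(FALSE, TRUE)) # separable held-out accuracy 1

  zero_head <- structure(
    list(coefficients = c(0, 0), threshold = 0.5, converged = TRUE),
    class = "lr_head"
  )
  expect_equal(head_prob(zero_head, matrix(5)), 0.5)
  expect_true(head_prob(zero_head, matrix(5)) >= zero_head$threshold)
})

test_that("the 80/20 protocol is stratified, leak-free and SMOTE-free at test", {
  feats <- default_features()
  rows <- feats[feats$patient_id == "P04", ][1:100, ]
  ev <- evaluate_split(rows, "lr", seed = 12)
  expect_equal(length(ev$test_idx), round(0.2 * sum(rows$label)) +
    round(0.2 * sum(!rows$label)))
  expect_length(intersect(ev$train_idx, ev$test_idx), 0)
  expect_setequal(c(ev$train_idx, ev$test_idx), seq_len(nrow(rows)))
  # class proportions within one sample of the full data
  expect_lte(
    abs(mean(rows$label[ev$test_idx]) - mean(rows$label)),
    1 / length(ev$test_idx) + 1e-9
  )
  expect_equal(nrow(ev$predictions), length(ev$test_idx))
  expect_true(all(ev$predictions$probability > 0 & ev$predictions$probability < 1))
  expect_error(evaluate_split(rows[1:40, ], "lr"), "at least 50")
  expect_error(evaluate_split(rows, "tllr", seed = 1), "required")
})
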