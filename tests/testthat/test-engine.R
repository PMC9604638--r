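# controllable stand-ins: a probability-returning function as classifier and
# an intercept-only quantile model
fixed_qr <- function(value, taus = c(0.2, 0.5)) {
  cf <- matrix(rep(value, length(taus)), 1, length(taus),
    dimnames = list("(Intercept)", sprintf("%g", taus))
  )
  structure(
    list(taus = taus, iterations = list(list(coefficients = cf))),
    class = "sliding_qr"
  )
}
feature_row <- data.frame(date = as.Date("2018-03-01"), x = 1)

test_that("engine config exposes its decision parameters explicitly", {
  cfg <- engine_config(median_pefr = 400)
  expect_equal(cfg$theta, 20) # 5% of the median
  expect_equal(cfg$tau_c, 0.2)
  expect_error(engine_config(), "supply 'theta'")
  expect_error(engine_config(tau_c = 1.2, theta = 10), "tau_c")
  expect_error(engine_config(theta = -1), "theta")
})

test_that("a low-probability day short-circuits without consulting the QR model", {
  rep0 <- daily_decision(
    function(rows) 0.3, fixed_qr(300), feature_row,
    previous_pefr_tau_c = 320, config = engine_config(theta = 30)
  )
  expect_equal(rep0$class, "noRisk")
  expect_false(rep0$qr_consulted)
  expect_true(is.na(rep0$pefr_tau_c))
  expect_false(rep0$alert)
})

test_that("alerts fire on large drops of the critical quantile only", {
  cfg <- engine_config(theta = 30)
  big_drop <- daily_decision(function(rows) 0.6, fixed_qr(280), feature_row, 320, cfg)
  expect_equal(big_drop$class, "risk")
  expect_true(big_drop$qr_consulted)
  expect_equal(big_drop$pefr_tau_c, 280)
  expect_equal(big_drop$drop, 40)
  expect_true(big_drop$alert)

  small_drop <- daily_decision(function(rows) 0.6, fixed_qr(315), feature_row, 320, cfg)
  expect_equal(small_drop$drop, 5)
  expect_false(small_drop$alert)

  expect_warning(
    no_prev <- daily_decision(function(rows) 0.6, fixed_qr(280), feature_row, NA, cfg),
    "no previous"
  )
  expect_true(is.na(no_prev$drop))
  expect_false(no_prev$alert)

  # boundary behaviour of theta
  inf_cfg <- engine_config(theta = Inf)
  expect_false(daily_decision(function(rows) 0.9, fixed_qr(100), feature_row, 500, inf_cfg)$alert)
  zero_cfg <- engine_config(theta = 0)
  expect_true(daily_decision(function(rows) 0.9, fixed_qr(319.9), feature_row, 320, zero_cfg)$alert)
})

test_that("update hooks receive every decision outcome", {
  seen <- new.env()
  seen$n <- 0
  cfg <- engine_config(theta = 10, update_hooks = list(function(r) {
    seen$n <- seen$n + 1
    seen$last <- r$class
  }))
  daily_decision(function(rows) 0.2, fixed_qr(300), feature_row, NA, cfg)
  daily_decision(function(rows) 0.8, fixed_qr(300), feature_row, 310, cfg)
  expect_equal(seen$n, 2)
  expect_equal(seen$last, "risk")
})

test_that("the pipeline run is reproducible and honours stage switches", {
  cfg <- cohort_config(
    n_patients = 4, days_range = c(70, 90), mean_days = 80,
    seed = 99
  )
  fast <- list(k = 3, epochs = 40, patience = 10)
  r1 <- run_pipeline(cfg,
    targets = c("P01", "P02"), seed = 5,
    window = window_spec(30, 15, 7), taus = c(0.2, 0.5),
    source_args = fast
  )
  expect_equal(sort(unique(r1$metrics$patient_id)), c("P01", "P02"))
  expect_setequal(unique(r1$metrics$method), c("lr", "tllr"))
  expect_equal(nrow(r1$metrics), 4)
  expect_false(is.null(r1$qr_errors))

  r2 <- run_pipeline(cfg,
    targets = c("P01", "P02"), seed = 5,
    window = window_spec(30, 15, 7), taus = c(0.2, 0.5),
    source_args = fast
  )
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$qr_errors, r2$qr_errors)

  qr_only <- run_pipeline(cfg,
    targets = "P01", seed = 5, run_classifier = FALSE,
    window = window_spec(30, 15, 7), taus = c(0.2, 0.5)
  )
  expect_null(qr_only$metrics)
  expect_false(is.null(qr_only$qr_errors))

  # engine invariants over the replayed daily reports
  for (id in names(r1$reports)) {
    reps <- r1$reports[[id]]
    consulted <- vapply(reps, function(r) r$qr_consulted, TRUE)
    risky <- vapply(reps, function(r) r$class == "risk", TRUE)
    alerts <- vapply(reps, function(r) isTRUE(r$alert), TRUE)
    expect_equal(consulted, risky) # QR consulted exactly on flagged days
    expect_lte(sum(alerts), sum(risky))
    expect_true(all(!alerts | risky))
  }
})
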