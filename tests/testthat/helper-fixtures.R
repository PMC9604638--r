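# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

# small, fast cohort for structural tests
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- simulate_cohort(cohort_config(
      n_patients = 4, days_range = c(70, 90), mean_days = 80, seed = 99
    ))
  }
  .fixtures$small
}

small_features <- function() {
  if (is.null(.fixtures$small_feats)) {
    .fixtures$small_feats <- build_cohort_features(small_cohort())
  }
  .fixtures$small_feats
}

# full-size default cohort: the calibration fixture
default_cohort <- function() {
  if (is.null(.fixtures$default)) {
    .fixtures$default <- simulate_cohort(cohort_config(seed = 2024))
  }
  .fixtures$default
}

default_features <- function() {
  if (is.null(.fixtures$default_feats)) {
    .fixtures$default_feats <- build_cohort_features(default_cohort())
  }
  .fixtures$default_feats
}

# deterministic tiny air-quality stream for exposure arithmetic
flat_records <- function(conc = 60, space = "living", t0 = as.POSIXct("2018-01-01 00:00:00", tz = "UTC"),
                         hours = 24, by = 120) {
  tt <- seq(t0, t0 + hours * 3600 - by, by = by)
  data.frame(
    timestamp = tt, space_id = space, pm25 = conc, co2 = 800,
    temperature = 22, humidity = 35, stringsAsFactors = FALSE
  )
}
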