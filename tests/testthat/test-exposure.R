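test_that("per-minute exposure rate follows conc * inh / 60 and is linear", {
  expect_equal(activity_exposure_rate(0, 0.012), 0)
  expect_equal(activity_exposure_rate(60, 1), 1)
  expect_equal(activity_exposure_rate(35.7, 0.5), 0.2975)
  expect_error(activity_exposure_rate(-1, 0.012), "non-negative")
  expect_error(activity_exposure_rate(10, 0), "positive")
  set.seed(1)
  a <- runif(20, 0, 100)
  r <- runif(20, 0.005, 0.05)
  expect_equal(activity_exposure_rate(2 * a, r), 2 * activity_exposure_rate(a, r))
  expect_equal(activity_exposure_rate(a, 3 * r), 3 * activity_exposure_rate(a, r))
})

test_that("accumulated exposure sums per-minute doses over activities", {
  t0 <- as.POSIXct("2018-01-01 00:00:00", tz = "UTC")
  rec <- flat_records(conc = 60) # E = 1/min at rate 1
  inh <- data.frame(activity_type = c("a", "b"), rate = c(1, 2))
  one <- data.frame(
    start = t0, end = t0 + 1800, activity_type = "a",
    space_id = "living", stringsAsFactors = FALSE
  )
  expect_equal(
    as.numeric(accumulate_daily_exposure(rec, one, inh, c(t0, t0 + 3600))), 30
  )

  # E = 1 and 2 per minute, 10 and 20 minutes -> 10 + 40 = 50
  two <- data.frame(
    start = c(t0, t0 + 600), end = c(t0 + 600, t0 + 1800),
    activity_type = c("a", "b"), space_id = "living",
    stringsAsFactors = FALSE
  )
  expect_equal(
    as.numeric(accumulate_daily_exposure(rec, two, inh, c(t0, t0 + 3600))), 50
  )

  none <- two[0, ]
  expect_equal(
    as.numeric(accumulate_daily_exposure(rec, none, inh, c(t0, t0 + 3600))), 0
  )
  expect_warning(
    z <- accumulate_daily_exposure(rec, two, inh, c(t0 + 10, t0)), "empty"
  )
  expect_equal(as.numeric(z), 0)

  # activity in a space with no records is skipped and counted
  far <- data.frame(
    start = t0, end = t0 + 1800, activity_type = "a",
    space_id = "garage", stringsAsFactors = FALSE
  )
  out <- accumulate_daily_exposure(rec, far, inh, c(t0, t0 + 3600))
  expect_equal(as.numeric(out), 0)
  expect_equal(attr(out, "activities_skipped"), 1)
})

test_that("accumulated exposure is additive over a partition of the window", {
  t0 <- as.POSIXct("2018-01-01 00:00:00", tz = "UTC")
  set.seed(3)
  rec <- flat_records()
  rec$pm25 <- runif(nrow(rec), 5, 80)
  inh <- data.frame(activity_type = "a", rate = 0.012)
  acts <- data.frame(
    start = t0 + seq(0, 23 * 3600, by = 3600),
    end = t0 + seq(3600, 24 * 3600, by = 3600),
    activity_type = "a", space_id = "living", stringsAsFactors = FALSE
  )
  whole <- accumulate_daily_exposure(rec, acts, inh, c(t0, t0 + 86400))
  half1 <- accumulate_daily_exposure(rec, acts, inh, c(t0, t0 + 43200))
  half2 <- accumulate_daily_exposure(rec, acts, inh, c(t0 + 43200, t0 + 86400))
  expect_equal(as.numeric(whole), as.numeric(half1) + as.numeric(half2))
})

test_that("window means match a brute-force oracle", {
  t0 <- as.POSIXct("2018-01-01 00:00:00", tz = "UTC")
  rec <- flat_records()
  rec$temperature <- 22.4
  expect_equal(mean_exposure(rec, "temperature", c(t0, t0 + 86400)), 22.4)

  rec2 <- rec[1:2, ]
  rec2$co2 <- c(20, 24)
  expect_equal(mean_exposure(rec2, "co2", c(t0, t0 + 86400)), 22)

  set.seed(9)
  rec3 <- flat_records(by = 120)
  rec3$humidity <- runif(nrow(rec3), 20, 60)
  rec3 <- rec3[runif(nrow(rec3)) > 0.1, ] # 10% removed
  w <- c(t0 + 3600, t0 + 9 * 3600)
  oracle <- {
    v <- c()
    for (i in seq_len(nrow(rec3))) {
      if (rec3$timestamp[i] >= w[1] && rec3$timestamp[i] < w[2]) {
        v <- c(v, rec3$humidity[i])
      }
    }
    mean(v)
  }
  expect_equal(mean_exposure(rec3, "humidity", w), oracle)
  expect_warning(
    m <- mean_exposure(rec3, "co2", c(t0 - 7200, t0 - 3600)), "flagged"
  )
  expect_true(is.na(m))
})

test_that("feature table has one row per day with a valid lookback window", {
  p <- small_cohort()$patients[[1]]
  tab <- build_feature_table(p)
  expect_equal(nrow(tab), p$n_days - 1) # first day has no lookback
  expect_equal(attr(tab, "n_dropped"), 0)
  expect_false(anyNA(tab[, c("pm25_dose", "co2_mean", "temp_mean", "rh_mean")]))

  # missing AM PEFR on day 5 drops the rows for days 5 and 6
  p2 <- p
  p2$pefr <- p$pefr[1:10, ]
  p2$pefr$am_pefr[5] <- NA
  tab2 <- build_feature_table(p2)
  expect_equal(nrow(tab2), 7)
  expect_equal(attr(tab2, "n_dropped"), 2)
  expect_false(p2$pefr$date[5] %in% tab2$date)
  expect_false(p2$pefr$date[6] %in% tab2$date)
})

test_that("no feature uses data at or after the day's AM measurement", {
  p <- small_cohort()$patients[[2]]
  tab <- build_feature_table(p)
  d <- 10
  am_d <- tab$am_time[tab$date == p$pefr$date[d]]
  # poison every record from AM of day d onward; row d must be unchanged
  p2 <- p
  late <- p2$air_quality$timestamp >= am_d
  expect_true(any(late))
  p2$air_quality$pm25[late] <- 1e6
  p2$air_quality$co2[late] <- 1e6
  tab2 <- build_feature_table(p2)
  i <- which(tab$date == p$pefr$date[d])
  expect_equal(tab2[i, c("pm25_dose", "co2_mean")], tab[i, c("pm25_dose", "co2_mean")])

  # time conservation: diary minutes inside any 24 h window cannot exceed 1440
  mins <- sum(as.numeric(p$activities$end - p$activities$start, units = "mins")[
    p$activities$start >= am_d - 86400 & p$activities$start < am_d
  ])
  expect_lte(mins, 1440)
})
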