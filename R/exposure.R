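#' Default inhalation-rate table
#'
#' Inhalation rate by activity type, in m3/min. The default ships a single
#' adult resting rate (0.012 m3/min) doubled for exertion-class activities
#' (cooking, chores, time out of the home); the table is an explicit input
#' so studies with measured, age-specific rates can substitute their own.
#'
#' @param rest_rate resting inhalation rate in m3/min.
#' @param exertion_factor multiplier for exertion-class activities.
#' @return data frame with columns `activity_type`, `rate`, `exertion`.
#' @export
default_inhalation_table <- function(rest_rate = 0.012, exertion_factor = 2) {
  data.frame(
    activity_type = c("sleep", "rest", "cook", "chores", "out"),
    rate = rest_rate * c(1, 1, exertion_factor, exertion_factor, exertion_factor),
    exertion = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Per-minute activity exposure rate
#'
#' The accumulated amount of environmental exposure per minute for an
#' activity: `E = conc * inh_rate / 60`, with the concentration sampled at
#' 60 s cadence. Linear in both arguments.
#'
#' @param conc environmental concentration (e.g. PM2.5 in ug/m3); must be
#'   non-negative.
#' @param inh_rate inhalation rate in m3/min; must be positive.
#' @return per-minute exposure (same vectorization as the inputs).
#' @export
activity_exposure_rate <- function(conc, inh_rate) {
  if (any(conc < 0, na.rm = TRUE)) stop("concentration must be non-negative")
  if (any(inh_rate <= 0, na.rm = TRUE)) stop("inhalation rate must be positive")
  conc * inh_rate / 60
}

# index of the nearest value of sorted 'ref' for each 'query'; NA beyond gap
nearest_index <- function(query, ref, max_gap) {
  if (!length(ref)) {
    return(rep(NA_integer_, length(query)))
  }
  i <- findInterval(query, ref)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(ref))
  pick <- ifelse(abs(query - ref[lo]) <= abs(ref[hi] - query), lo, hi)
  pick[abs(query - ref[pick]) > max_gap] <- NA_integer_
  pick
}

#' Accumulated exposure over a time window
#'
#' Implements the daily dose `f = sum_j E_j T_j`: within each activity
#' interval, every minute is matched to the nearest concentration record in
#' the interval's space (within `max_gap` seconds; unmatched minutes are
#' skipped and counted), converted to a per-minute exposure via
#' [activity_exposure_rate()] with the activity's inhalation rate, and
#' summed. Activities referencing a space with no sensor records are
#' skipped and counted.
#'
#' @param records air-quality data frame (`timestamp`, `space_id`, and the
#'   concentration column `variable`).
#' @param activities activity-diary data frame (`start`, `end`,
#'   `activity_type`, `space_id`).
#' @param inh inhalation table (see [default_inhalation_table()]).
#' @param window length-2 vector (POSIXct or numeric seconds), the
#'   half-open interval `[t0, t1)` to accumulate over.
#' @param variable concentration column (default `"pm25"`).
#' @param max_gap largest record-to-minute gap accepted, in seconds.
#' @return the accumulated dose, with attributes `minutes_used`,
#'   `minutes_skipped` and `activities_skipped`.
#' @export
accumulate_daily_exposure <- function(records, activities, inh, window,
                                      variable = "pm25", max_gap = 600) {
  t0 <- as.numeric(window[1])
  t1 <- as.numeric(window[2])
  if (t1 <= t0) {
    warning("empty exposure window; returning zero")
    return(structure(0,
      minutes_used = 0L, minutes_skipped = 0L,
      activities_skipped = 0L
    ))
  }
  a_start <- pmax(as.numeric(activities$start), t0)
  a_end <- pmin(as.numeric(activities$end), t1)
  keep <- a_end > a_start
  acts <- activities[keep, , drop = FALSE]
  a_start <- a_start[keep]
  a_end <- a_end[keep]
  if (!nrow(acts)) {
    return(structure(0,
      minutes_used = 0L, minutes_skipped = 0L,
      activities_skipped = 0L
    ))
  }
  rate <- inh$rate[match(acts$activity_type, inh$activity_type)]
  if (anyNA(rate)) {
    stop(
      "activity types missing from inhalation table: ",
      paste(unique(acts$activity_type[is.na(rate)]), collapse = ", ")
    )
  }

  n_min <- as.integer((a_end - a_start) %/% 60)
  idx <- rep(seq_len(nrow(acts)), n_min)
  minute_t <- a_start[idx] + (sequence(n_min) - 1) * 60

  rec_t <- as.numeric(records$timestamp)
  conc_total <- 0
  used <- 0L
  skipped <- 0L
  act_skipped <- 0L
  for (sp in unique(acts$space_id)) {
    in_sp <- acts$space_id[idx] == sp
    sel <- which(records$space_id == sp)
    if (!length(sel)) {
      act_skipped <- act_skipped + length(unique(idx[in_sp]))
      skipped <- skipped + sum(in_sp)
      next
    }
    o <- sel[order(rec_t[sel])]
    ni <- nearest_index(minute_t[in_sp], rec_t[o], max_gap)
    ok <- !is.na(ni)
    conc <- records[[variable]][o][ni[ok]]
    conc_total <- conc_total +
      sum(activity_exposure_rate(conc, rate[idx[in_sp]][ok]))
    used <- used + sum(ok)
    skipped <- skipped + sum(!ok)
  }
  structure(conc_total,
    minutes_used = used, minutes_skipped = skipped,
    activities_skipped = act_skipped
  )
}

#' Mean of an air-quality variable over a window
#'
#' Plain arithmetic mean of the in-window records; used for the daily CO2,
#' temperature and humidity summaries (and optionally for PM2.5 when the
#' dose aggregation is switched off).
#'
#' @param records air-quality data frame.
#' @param variable one of `"co2"`, `"temperature"`, `"humidity"`, `"pm25"`.
#' @param window half-open interval `[t0, t1)`.
#' @return the mean, or `NA` (with a warning) when no record falls in the
#'   window.
#' @export
mean_exposure <- function(records, variable = c("co2", "temperature", "humidity", "pm25"),
                          window) {
  variable <- match.arg(variable)
  t <- as.numeric(records$timestamp)
  sel <- t >= as.numeric(window[1]) & t < as.numeric(window[2])
  if (!any(sel)) {
    warning(sprintf("no %s records in window; row should be flagged", variable))
    return(NA_real_)
  }
  mean(records[[variable]][sel])
}

#' Build the daily feature table for one patient
#'
#' One row per diary day `d >= 2`, aggregating exposures over the 24 h
#' window between yesterday's and today's AM PEFR measurement times
#' (half-open, `[AM_{d-1}, AM_d)`), so no feature uses data at or after the
#' morning measurement it predicts. PM2.5 enters as the inhalation-weighted
#' accumulated dose; CO2, temperature and humidity as window means. Rows
#' whose own or previous-day AM PEFR is missing are dropped and counted.
#'
#' @param patient a `synthetic_patient`, or any list with data frames
#'   `air_quality`, `pefr`, `activities` and one-row `covariates` in the
#'   package's column schemas.
#' @param inh inhalation table.
#' @param max_gap largest record-to-minute matching gap, seconds.
#' @param am_hour hour of day of the AM measurement when the PEFR diary has
#'   no `am_time` column.
#' @param pm25_as_mean if `TRUE`, replace the dose aggregate with the plain
#'   24 h PM2.5 mean.
#' @return data frame of daily feature rows (`patient_id`, `date`,
#'   `am_time`, `pm25_dose`, `co2_mean`, `temp_mean`, `rh_mean`,
#'   `yesterday_am_pefr`, `yesterday_pm_pefr`, covariates, `am_pefr`), with
#'   attributes `n_dropped` (missing-PEFR rows) and `minutes_skipped`.
#' @export
build_feature_table <- function(patient, inh = default_inhalation_table(),
                                max_gap = 600, am_hour = 8,
                                pm25_as_mean = FALSE) {
  pefr <- patient$pefr
  air <- patient$air_quality
  acts <- patient$activities
  cov <- patient$covariates
  if (nrow(pefr) < 2) stop("need at least 2 diary days")
  am_time <- if ("am_time" %in% names(pefr)) {
    as.numeric(pefr$am_time)
  } else {
    as.numeric(as.POSIXct(paste(pefr$date, "00:00:00"), tz = "UTC")) +
      am_hour * 3600
  }
  n <- nrow(pefr)
  rec_t <- as.numeric(air$timestamp)

  # window index per record: record in [AM_w, AM_{w+1}) feeds day w+1
  win_rec <- findInterval(rec_t, am_time)
  in_rec <- win_rec >= 1 & win_rec <= n - 1
  wmean <- function(v) {
    out <- rep(NA_real_, n - 1)
    m <- tapply(v[in_rec], win_rec[in_rec], mean)
    out[as.integer(names(m))] <- as.numeric(m)
    out
  }
  co2_mean <- wmean(air$co2)
  temp_mean <- wmean(air$temperature)
  rh_mean <- wmean(air$humidity)

  minutes_skipped <- 0L
  if (pm25_as_mean) {
    pm25_dose <- wmean(air$pm25)
  } else {
    # minute grid over the whole span, matched to records per space
    a_start <- as.numeric(acts$start)
    a_end <- as.numeric(acts$end)
    span0 <- am_time[1]
    span1 <- am_time[n]
    minute_t <- seq(span0, span1 - 60, by = 60)
    ai <- findInterval(minute_t, a_start)
    valid <- ai >= 1 & minute_t < a_end[pmax(ai, 1)]
    rate <- inh$rate[match(acts$activity_type, inh$activity_type)]
    if (anyNA(rate)) {
      stop(
        "activity types missing from inhalation table: ",
        paste(unique(acts$activity_type[is.na(rate)]), collapse = ", ")
      )
    }
    conc <- rep(NA_real_, length(minute_t))
    for (sp in unique(acts$space_id)) {
      sel_m <- which(valid & acts$space_id[ai] == sp)
      if (!length(sel_m)) next
      rsel <- which(air$space_id == sp)
      o <- rsel[order(rec_t[rsel])]
      ni <- nearest_index(minute_t[sel_m], rec_t[o], max_gap)
      conc[sel_m] <- air$pm25[o][ni]
    }
    e_min <- activity_exposure_rate(pmax(conc, 0), rate[pmax(ai, 1)])
    e_min[!valid | is.na(conc)] <- NA
    minutes_skipped <- sum(is.na(e_min))
    win_min <- findInterval(minute_t, am_time)
    ok <- !is.na(e_min) & win_min >= 1 & win_min <= n - 1
    pm25_dose <- rep(NA_real_, n - 1)
    s <- tapply(e_min[ok], win_min[ok], sum)
    pm25_dose[as.integer(names(s))] <- as.numeric(s)
  }

  d <- 2:n
  rows <- data.frame(
    patient_id = cov$patient_id,
    date = pefr$date[d],
    am_time = as.POSIXct(am_time[d], origin = "1970-01-01", tz = "UTC"),
    pm25_dose = pm25_dose[d - 1],
    co2_mean = co2_mean[d - 1],
    temp_mean = temp_mean[d - 1],
    rh_mean = rh_mean[d - 1],
    yesterday_am_pefr = pefr$am_pefr[d - 1],
    yesterday_pm_pefr = ifelse(is.na(pefr$pm_pefr[d - 1]),
      pefr$am_pefr[d - 1], pefr$pm_pefr[d - 1]
    ),
    age = cov$age,
    sex = as.integer(cov$sex == "M"),
    bmi = cov$bmi,
    cooking_level = cov$cooking_level,
    road_level = cov$road_level,
    income_level = cov$income_level,
    am_pefr = pefr$am_pefr[d],
    stringsAsFactors = FALSE
  )
  keep <- !is.na(rows$am_pefr) & !is.na(rows$yesterday_am_pefr)
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "minutes_skipped") <- minutes_skipped
  out
}

#' Build and label feature tables for a whole cohort
#'
#' Runs [build_feature_table()] for every patient and, if requested,
#' derives each patient's critical PEFR value from their own rows and
#' labels risk days.
#'
#' @param cohort a `synthetic_cohort` (or list of patient stream lists).
#' @param label if `TRUE`, append per-patient risk labels via
#'   [critical_pefr()] and [label_days()] at the cohort config's risk
#'   quantile (or `q`).
#' @param q risk quantile override.
#' @param ... passed to [build_feature_table()].
#' @return one data frame of daily feature rows for all patients.
#' @export
build_cohort_features <- function(cohort, label = TRUE, q = NULL, ...) {
  patients <- if (inherits(cohort, "synthetic_cohort")) cohort$patients else cohort
  if (is.null(q)) {
    q <- if (inherits(cohort, "synthetic_cohort")) {
      cohort$config$risk_quantile
    } else {
      0.2
    }
  }
  tabs <- lapply(patients, function(p) {
    tab <- build_feature_table(p, ...)
    if (label) {
      zon <- critical_pefr(tab$am_pefr, q = q)
      tab <- label_days(tab, zon)
    }
    tab
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
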