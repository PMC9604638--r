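#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded simulation never
#' perturbs the global stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# derived per-patient seed, kept well below 2^31
seed_for <- function(seed, idx) {
  as.integer(((seed %% 1000003) * 1009 + idx * 7919) %% 2147483629 + 1)
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the structure of the reference study cohort: 19 adult
#' asthma patients monitored over one winter-spring season, per-patient
#' diary lengths between 118 and 212 days with a cohort mean near 154 days,
#' cohort median AM PEFR near 373 L/min, and daily-mean indoor exposures
#' centred near 35.7 ug/m3 PM2.5, 887 ppm CO2, 22.4 C and 33% RH. Indoor
#' pollutant dynamics are mean-reverting (day-level AR(1) plus a
#' within-day Ornstein-Uhlenbeck component at sensor cadence) with
#' activity-linked bursts: cooking raises kitchen PM2.5, occupancy and
#' sleep raise CO2. Next-day AM PEFR is generated causally from the
#' previous 24 h window of aggregated exposures:
#' `AM_d = baseline_i + ar (AM_{d-1} - baseline_i) +
#'   sum_v effect_v (x_{v,d-1} - center_v) + noise`.
#'
#' @param n_patients cohort size.
#' @param days_range inclusive range the per-patient diary length is drawn
#'   from.
#' @param mean_days target cohort mean diary length.
#' @param sensor_interval sensor cadence in seconds (60 or 120).
#' @param pefr_baseline_median population median of patient AM baselines
#'   (L/min).
#' @param pefr_between_sd between-patient baseline spread (L/min).
#' @param pefr_sd day-to-day PEFR noise (L/min).
#' @param ar autoregressive persistence of the daily AM PEFR anomaly.
#' @param effects named per-variable exposure effects, in delta-PEFR
#'   (L/min) per unit of the daily exposure feature (PM2.5 inhaled dose,
#'   CO2 ppm, temperature C, RH %). Set to zeros for a null generator.
#' @param effect_heterogeneity between-patient SD of the multiplicative
#'   effect perturbation (shared signs, patient-specific magnitudes).
#' @param risk_quantile fraction of each patient's own PEFR distribution
#'   defining the risk zone.
#' @param missing_frac fraction of sensor records dropped uniformly at
#'   random (gap-handling exercise; default 0).
#' @param start_date first diary date.
#' @param seed integer RNG seed for the whole cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 19,
                          days_range = c(118, 212),
                          mean_days = 154,
                          sensor_interval = 120,
                          pefr_baseline_median = 373.3,
                          pefr_between_sd = 40,
                          pefr_sd = 18,
                          ar = 0.45,
                          effects = c(
                            pm25_dose = -1.2,
                            co2_mean = -0.03,
                            temp_mean = 2.0,
                            rh_mean = -0.5
                          ),
                          effect_heterogeneity = 0.15,
                          risk_quantile = 0.2,
                          missing_frac = 0,
                          start_date = as.Date("2017-11-01"),
                          seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (length(days_range) != 2 || days_range[1] < 2 || days_range[2] < days_range[1]) {
    stop("days_range must be an increasing pair with minimum >= 2")
  }
  if (!sensor_interval %in% c(60, 120)) {
    stop("sensor_interval must be 60 or 120 seconds")
  }
  if (risk_quantile <= 0 || risk_quantile >= 1) {
    stop("risk_quantile must be in (0, 1)")
  }
  if (mean_days < days_range[1] || mean_days > days_range[2]) {
    stop("mean_days must lie inside days_range")
  }
  if (missing_frac < 0 || missing_frac >= 1) stop("missing_frac must be in [0, 1)")
  need <- c("pm25_dose", "co2_mean", "temp_mean", "rh_mean")
  if (!all(need %in% names(effects))) {
    stop("effects must be named: ", paste(need, collapse = ", "))
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    days_range = as.integer(days_range),
    mean_days = mean_days,
    sensor_interval = as.integer(sensor_interval),
    pefr_baseline_median = pefr_baseline_median,
    pefr_between_sd = pefr_between_sd,
    pefr_sd = pefr_sd,
    ar = ar,
    effects = effects[need],
    effect_heterogeneity = effect_heterogeneity,
    risk_quantile = risk_quantile,
    missing_frac = missing_frac,
    start_date = as.Date(start_date),
    seed = as.integer(seed),
    # population centres the exposure effects are taken relative to
    feature_centers = c(
      pm25_dose = 10.3, co2_mean = 887, temp_mean = 22.4, rh_mean = 32.7
    ),
    am_hour = 8, pm_hour = 20
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort config: %d patients, %d-%d days (mean target %g), sensor every %d s, seed %d\n",
    x$n_patients, x$days_range[1], x$days_range[2], x$mean_days,
    x$sensor_interval, x$seed
  ))
  invisible(x)
}

# activity codes for one day of 48 half-hour slots
day_slots <- function(cook_breakfast, cook_lunch, cook_dinner, out_day) {
  act <- rep("rest", 48)
  act[1:14] <- "sleep" # 00:00-07:00
  if (cook_breakfast) act[16] <- "cook" # 07:30-08:00
  if (out_day) act[21:24] <- "out" # 10:00-12:00
  if (cook_lunch) act[25] <- "cook" # 12:00-12:30
  act[31:32] <- "chores" # 15:00-16:00
  if (cook_dinner) act[38] <- "cook" # 18:30-19:00
  act[45:48] <- "sleep" # 22:00-24:00
  act
}

space_of_activity <- function(act) {
  c(
    sleep = "bedroom", rest = "living", cook = "kitchen",
    chores = "living", out = "out"
  )[act]
}

# recursive AR(1) series x_t = mu + phi (x_{t-1} - mu) + e_t; callers
# discard a burn-in to approximate the stationary start
ar1_series <- function(n, mu, phi, sd) {
  e <- stats::rnorm(n, 0, sd)
  mu + as.numeric(stats::filter(e, phi, method = "recursive"))
}

#' Simulate one synthetic patient
#'
#' Generates the three per-patient data streams the framework consumes: a
#' sensor stream of indoor air-quality records at the configured cadence
#' (absent while the patient is out of the home), a 30-minute activity
#' diary tiling each day, and a twice-daily PEFR diary with the causal
#' exposure link described in [cohort_config()]. Fully deterministic given
#' `(config, config$seed, patient_id)`.
#'
#' @param config a [cohort_config()].
#' @param patient_id identifier such as `"P07"`; its numeric suffix indexes
#'   the patient within the cohort.
#' @return An object of class `synthetic_patient`: list with `patient_id`,
#'   data frames `air_quality` (timestamp, space_id, pm25, co2,
#'   temperature, humidity), `pefr` (date, am_pefr, pm_pefr), `activities`
#'   (start, end, activity_type, space_id), and one-row `covariates`.
#' @export
simulate_patient <- function(config, patient_id) {
  stopifnot(inherits(config, "cohort_config"))
  idx <- suppressWarnings(as.integer(gsub("[^0-9]", "", patient_id)))
  if (is.na(idx)) idx <- sum(utf8ToInt(patient_id)) %% 1000L
  with_seed(seed_for(config$seed, idx), {
    rng <- config$days_range
    span <- rng[2] - rng[1]
    n_days <- if (span == 0) {
      rng[1]
    } else {
      rng[1] + stats::rbinom(1, span, (config$mean_days - rng[1]) / span)
    }

    # ---- static covariates -------------------------------------------------
    sex <- if (idx %% 2 == 1) "F" else "M" # ~10/9 split over 19 ids
    covariates <- data.frame(
      patient_id = patient_id,
      age = sample(34:83, 1),
      sex = sex,
      bmi = round(stats::rnorm(1, 24, 2.8), 1),
      cooking_level = sample(1:7, 1),
      road_level = sample(1:5, 1),
      income_level = sample(1:9, 1),
      stringsAsFactors = FALSE
    )
    baseline <- config$pefr_baseline_median +
      ifelse(sex == "M", 45, -45) +
      stats::rnorm(1, 0, config$pefr_between_sd)
    eff <- config$effects *
      stats::rnorm(length(config$effects), 1, config$effect_heterogeneity)

    # ---- activity diary ----------------------------------------------------
    cook_prob <- (8 - covariates$cooking_level) / 7
    cook_day <- stats::runif(n_days) < cook_prob
    lunch_day <- cook_day & stats::runif(n_days) < 0.5
    out_day <- stats::runif(n_days) < 0.2
    acts <- unlist(lapply(seq_len(n_days), function(d) {
      day_slots(cook_day[d], lunch_day[d], cook_day[d], out_day[d])
    }))
    slot0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
    starts <- slot0 + (seq_along(acts) - 1) * 1800
    activities <- data.frame(
      start = starts, end = starts + 1800,
      activity_type = acts, space_id = unname(space_of_activity(acts)),
      stringsAsFactors = FALSE
    )

    # ---- sensor stream -----------------------------------------------------
    step <- config$sensor_interval
    spd <- 86400L %/% step
    n_steps <- n_days * spd
    tt <- slot0 + (seq_len(n_steps) - 1) * step
    day_of <- rep(seq_len(n_days), each = spd)
    tod <- (as.numeric(tt - slot0) %% 86400) / 3600 # hour of day
    act_step <- acts[pmin(length(acts), (seq_len(n_steps) - 1) %/% (1800 / step) + 1)]

    ou <- function(sd_stat, tau_minutes) {
      rho <- exp(-step / (tau_minutes * 60))
      e <- stats::rnorm(n_steps, 0, sd_stat * sqrt(1 - rho^2))
      as.numeric(stats::filter(e, rho, method = "recursive"))
    }
    daily <- function(mu, phi, sd) {
      x <- ar1_series(n_days + 20, mu, phi, sd)[-(1:20)]
      x[day_of]
    }

    # PM2.5: lognormal base + cooking pulses decaying over ~45 min
    lpm <- daily(log(29), 0.6, 0.25) + 0.12 * sin(2 * pi * (tod - 12) / 24) +
      ou(0.20, 40)
    pm <- exp(lpm)
    pulse <- numeric(n_steps)
    cook_idx <- which(act_step == "cook")
    if (length(cook_idx)) {
      ev <- cook_idx[c(TRUE, diff(cook_idx) > 1)] # first step of each event
      amp <- stats::rlnorm(length(ev), log(70), 0.4)
      horizon <- ceiling(180 * 60 / step)
      decay <- exp(-(0:horizon) * step / (45 * 60))
      for (i in seq_along(ev)) {
        span_i <- ev[i]:min(n_steps, ev[i] + horizon)
        pulse[span_i] <- pulse[span_i] + amp[i] * decay[seq_along(span_i)]
      }
    }
    pm <- pm + pulse

    # CO2: base + occupancy terms (home adds ~120 ppm, sleep ~260 more)
    co2 <- exp(daily(log(700), 0.6, 0.12) + ou(0.06, 60)) +
      120 * (act_step != "out") + 260 * (act_step == "sleep")

    season <- -1.2 * cos(2 * pi * (day_of - 75) / 212) # mild indoor seasonality
    temp <- daily(22.4, 0.7, 0.8) + season +
      0.8 * sin(2 * pi * (tod - 15) / 24) + ou(0.3, 60)
    rh <- daily(32.7, 0.7, 4) - 0.6 * sin(2 * pi * (tod - 15) / 24) + ou(1.5, 60)
    rh <- pmin(95, pmax(5, rh))
    pm <- pmax(pm, 0.5)
    co2 <- pmax(co2, 350)

    keep <- act_step != "out"
    if (config$missing_frac > 0) {
      keep <- keep & stats::runif(n_steps) >= config$missing_frac
    }
    air <- data.frame(
      timestamp = tt[keep],
      space_id = unname(space_of_activity(act_step[keep])),
      pm25 = round(pm[keep], 2),
      co2 = round(co2[keep], 1),
      temperature = round(temp[keep], 2),
      humidity = round(rh[keep], 2),
      stringsAsFactors = FALSE
    )

    # ---- daily exposures driving PEFR -------------------------------------
    # 24 h window [AM_{d-1}, AM_d); the generator aggregates its own stream
    # at sensor cadence with the same inhalation weighting the featurizer
    # applies per minute.
    inh <- default_inhalation_table()
    rate_step <- inh$rate[match(act_step, inh$activity_type)]
    e_step <- pm * rate_step / 60 * (step / 60) # dose accrued per step
    am_bound <- as.numeric(slot0) + (seq_len(n_days + 1) - 1) * 86400 +
      config$am_hour * 3600
    win <- findInterval(as.numeric(tt), am_bound) # 0 = before day-1 AM
    in_win <- win >= 1 & win <= n_days - 1 & keep
    agg <- function(v, f = sum) {
      out <- rep(NA_real_, n_days - 1)
      s <- tapply(v[in_win], win[in_win], f)
      out[as.integer(names(s))] <- as.numeric(s)
      out
    }
    dose <- agg(e_step) # window w feeds PEFR of day w+1
    co2m <- agg(co2, mean)
    tm <- agg(temp, mean)
    rhm <- agg(rh, mean)

    expo_effect <- eff["pm25_dose"] * (dose - config$feature_centers["pm25_dose"]) +
      eff["co2_mean"] * (co2m - config$feature_centers["co2_mean"]) +
      eff["temp_mean"] * (tm - config$feature_centers["temp_mean"]) +
      eff["rh_mean"] * (rhm - config$feature_centers["rh_mean"])
    expo_effect[is.na(expo_effect)] <- 0

    am <- numeric(n_days)
    noise <- stats::rnorm(n_days, 0, config$pefr_sd)
    stat_sd <- sqrt(config$pefr_sd^2 / (1 - config$ar^2))
    am[1] <- baseline + stats::rnorm(1, 0, stat_sd)
    for (d in 2:n_days) {
      am[d] <- baseline + config$ar * (am[d - 1] - baseline) +
        expo_effect[d - 1] + noise[d]
    }
    pm_pefr <- am + 8 + stats::rnorm(n_days, 0, 9)
    pefr <- data.frame(
      date = config$start_date + seq_len(n_days) - 1,
      am_pefr = round(am, 1),
      pm_pefr = round(pm_pefr, 1)
    )

    out <- list(
      patient_id = patient_id,
      air_quality = air,
      pefr = pefr,
      activities = activities,
      covariates = covariates,
      baseline = baseline,
      effects = eff,
      n_days = n_days
    )
    class(out) <- "synthetic_patient"
    out
  })
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf(
    "Synthetic patient %s: %d diary days, %d sensor records, AM PEFR median %.1f L/min\n",
    x$patient_id, x$n_days, nrow(x$air_quality),
    stats::median(x$pefr$am_pefr)
  ))
  invisible(x)
}

#' Simulate a synthetic cohort
#'
#' Patients share population-level structure (common effect directions and
#' pollutant dynamics) with patient-specific baselines, diary lengths and
#' effect magnitudes, so that pooling other patients' data for transfer
#' learning is meaningful. With `n_patients = 1` the pooled set excluding
#' the target is empty; downstream training flags this.
#'
#' @param config a [cohort_config()].
#' @return An object of class `synthetic_cohort`: list of
#'   `synthetic_patient` objects, with the config attached.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- sprintf("P%02d", seq_len(config$n_patients))
  patients <- lapply(ids, function(id) simulate_patient(config, id))
  names(patients) <- ids
  structure(list(patients = patients, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  nd <- vapply(x$patients, function(p) p$n_days, 0L)
  med <- stats::median(vapply(
    x$patients,
    function(p) stats::median(p$pefr$am_pefr), 0
  ))
  cat(sprintf(
    "Synthetic cohort: %d patients, %d-%d days (mean %.1f), median patient AM PEFR %.1f L/min\n",
    length(x$patients), min(nd), max(nd), mean(nd), med
  ))
  invisible(x)
}
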