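# CSV schemas (comma-separated, UTF-8, ISO-8601 timestamps):
#   air_quality.csv: timestamp, space_id, pm25, co2, temperature, humidity
#   pefr.csv:        date, am_pefr, pm_pefr
#   activities.csv:  start, end, activity_type, space_id
#   covariates.csv:  patient_id, age, sex, bmi, cooking_level, road_level,
#                    income_level

iso_dt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Write one patient's data streams as CSV
#'
#' @param patient a `synthetic_patient` (or compatible list).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_patient_csv <- function(patient, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  air <- patient$air_quality
  air$timestamp <- iso_dt(air$timestamp)
  act <- patient$activities
  act$start <- iso_dt(act$start)
  act$end <- iso_dt(act$end)
  paths <- c(
    air_quality = file.path(dir, "air_quality.csv"),
    pefr = file.path(dir, "pefr.csv"),
    activities = file.path(dir, "activities.csv"),
    covariates = file.path(dir, "covariates.csv")
  )
  utils::write.csv(air, paths["air_quality"], row.names = FALSE)
  utils::write.csv(patient$pefr, paths["pefr"], row.names = FALSE)
  utils::write.csv(act, paths["activities"], row.names = FALSE)
  utils::write.csv(patient$covariates, paths["covariates"], row.names = FALSE)
  invisible(paths)
}

#' Read one patient's data streams from CSV
#'
#' @param dir directory holding the four schema files.
#' @return a list compatible with [build_feature_table()].
#' @export
read_patient_csv <- function(dir) {
  air <- utils::read.csv(file.path(dir, "air_quality.csv"),
    stringsAsFactors = FALSE
  )
  air$timestamp <- as.POSIXct(air$timestamp,
    format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"
  )
  pefr <- utils::read.csv(file.path(dir, "pefr.csv"), stringsAsFactors = FALSE)
  pefr$date <- as.Date(pefr$date)
  act <- utils::read.csv(file.path(dir, "activities.csv"),
    stringsAsFactors = FALSE
  )
  act$start <- as.POSIXct(act$start, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  act$end <- as.POSIXct(act$end, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  cov <- utils::read.csv(file.path(dir, "covariates.csv"),
    stringsAsFactors = FALSE,
    colClasses = c(sex = "character") # "F" must not parse as FALSE
  )
  structure(
    list(
      patient_id = cov$patient_id[1], air_quality = air, pefr = pefr,
      activities = act, covariates = cov
    ),
    class = "synthetic_patient"
  )
}

#' Write a whole cohort plus manifest
#'
#' One sub-directory per patient and a `manifest.json` recording the seed,
#' config and patient ids.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    write_patient_csv(p, file.path(dir, p$patient_id))
  }
  cfg <- cohort$config
  jsonlite::write_json(
    list(
      package_version = as.character(utils::packageVersion("pefrisk")),
      seed = cfg$seed, n_patients = cfg$n_patients,
      sensor_interval = cfg$sensor_interval,
      patient_ids = names(cohort$patients),
      days = vapply(cohort$patients, function(p) p$n_days, 0L)
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
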