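# Strict CSV schemas shared by the simulator and the analysis stages.
# Decimal point, UTF-8, exact headers; violations are reported with the
# offending columns or row numbers.

measurement_cols <- c("subject_id", "level", "frequency_khz", "delta_v_i_mv",
                      "replicate")
areas_cols <- c("subject_id", "level", "vf_area_cm2", "sf_area_cm2")
subjects_cols <- c("subject_id", "sex", "age_y", "bmi", "wc_cm", "weight_kg")

read_strict_csv <- function(path, expected, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!identical(names(df)[seq_along(expected)], expected)) {
    stop(what, " schema violation in ", path, ": expected header ",
         paste(expected, collapse = ","), " but found ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  if (!nrow(df)) stop(what, " file ", path, " has no data rows", call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Read a replicate measurement table
#'
#' One row per replicate: `subject_id, level, frequency_khz, delta_v_i_mv,
#' replicate`. Levels must be among [bela_levels()]; voltage changes are
#' positive loss magnitudes.
#'
#' @param path CSV path.
#' @return Data frame of raw measurements.
#' @export
read_measurements_csv <- function(path) {
  df <- read_strict_csv(path, measurement_cols, "measurement")
  check_level(df$level)
  bad <- which(!is.finite(df$delta_v_i_mv) | df$delta_v_i_mv < 0)
  if (length(bad)) {
    stop("measurement rows with invalid delta_v_i_mv (row ",
         paste(utils::head(bad, 5L), collapse = ", "), ")", call. = FALSE)
  }
  if (any(df$replicate < 1)) stop("replicate index must be >= 1", call. = FALSE)
  df
}

#' Read an MRI fat-areas table
#'
#' One row per subject and level: `subject_id, level, vf_area_cm2,
#' sf_area_cm2`.
#'
#' @param path CSV path.
#' @return Data frame of fat areas.
#' @export
read_areas_csv <- function(path) {
  df <- read_strict_csv(path, areas_cols, "fat-areas")
  check_level(df$level)
  if (any(df$vf_area_cm2 < 0 | df$sf_area_cm2 < 0)) {
    stop("fat areas must be non-negative", call. = FALSE)
  }
  df
}

#' Read a subjects (anthropometrics) table
#'
#' One row per subject: `subject_id, sex, age_y, bmi, wc_cm, weight_kg`.
#'
#' @param path CSV path.
#' @return Data frame of subject records.
#' @export
read_subjects_csv <- function(path) {
  df <- read_strict_csv(path, subjects_cols, "subjects")
  if (any(df$bmi <= 0 | df$wc_cm <= 0)) {
    stop("bmi and wc_cm must be positive", call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject ids in subjects table", call. = FALSE)
  }
  df
}

#' Write a simulated cohort to its canonical files
#'
#' Writes `measurements.csv`, `areas.csv`, `subjects.csv`,
#' `ground_truth.json` and `manifest.json` into a directory. The CSVs are the
#' exact schemas the analysis stages consume; ground truth and the
#' configuration manifest travel alongside so every downstream number is
#' reproducible from the directory alone.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(measurements = file.path(dir, "measurements.csv"),
             areas = file.path(dir, "areas.csv"),
             subjects = file.path(dir, "subjects.csv"),
             ground_truth = file.path(dir, "ground_truth.json"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(cohort$measurements, paths["measurements"],
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(cohort$areas, paths["areas"], row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  subj <- cohort$subjects[subjects_cols]
  utils::write.csv(subj, paths["subjects"], row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  jsonlite::write_json(cohort$ground_truth, paths["ground_truth"],
                       digits = NA, dataframe = "rows")
  jsonlite::write_json(cohort$manifest, paths["manifest"], digits = NA,
                       auto_unbox = TRUE)
  invisible(paths)
}

#' Simulate a cohort and write its files in one step
#'
#' Convenience wrapper around [simulate_cohort()] and [write_cohort_files()].
#'
#' @param dir Output directory.
#' @param ... Passed to [simulate_cohort()] (`n`, `seed`, configs, ...).
#' @return Invisibly, a list with the cohort object and the file paths.
#' @export
simulate_cohort_files <- function(dir, ...) {
  cohort <- simulate_cohort(...)
  paths <- write_cohort_files(cohort, dir)
  invisible(list(cohort = cohort, paths = paths))
}
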