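#' Per-subject, per-level loss-rate table
#'
#' Aggregates a replicate measurement table to one row per subject and level:
#' the loss changing rate, its half-range repeatability, the relative
#' repeatability in percent, and the replicate count. Subjects whose rows are
#' incomplete (for instance missing one frequency at a level) are reported
#' and skipped; all complete subjects are still processed.
#'
#' @param measurements Raw measurement data frame (schema of
#'   [read_measurements_csv()]) or a path to such a CSV.
#' @param freqs A [frequency_pair()].
#' @return Data frame with `subject_id`, `level`, `mean_dv_L`, `mean_dv_H`,
#'   `sigma_L`, `sigma_H`, `n_replicates`, `m_loss`, `delta_m_loss`,
#'   `relative_repeatability_pct`, `negative_m_loss`.
#' @export
loss_rate_table <- function(measurements, freqs = frequency_pair()) {
  if (is.character(measurements)) {
    measurements <- read_measurements_csv(measurements)
  }
  groups <- split(measurements,
                  list(measurements$subject_id, measurements$level),
                  drop = TRUE)
  rows <- list()
  failed <- character()
  for (g in groups) {
    lm_ <- tryCatch(aggregate_replicates(g, freqs), error = function(e) e)
    if (inherits(lm_, "error")) {
      failed <- c(failed, sprintf("%s/%s: %s", g$subject_id[1], g$level[1],
                                  conditionMessage(lm_)))
      next
    }
    rows[[length(rows) + 1L]] <- lm_
  }
  if (length(failed)) {
    warning("skipped subject/level group(s):\n  ",
            paste(failed, collapse = "\n  "), call. = FALSE)
  }
  if (!length(rows)) stop("no complete subject/level groups", call. = FALSE)
  tab <- do.call(rbind, rows)
  tab$m_loss <- suppressWarnings(
    compute_m_loss(tab$mean_dv_H, tab$mean_dv_L, freqs))
  tab$delta_m_loss <- compute_repeatability(tab$sigma_H, tab$sigma_L, freqs)
  tab$relative_repeatability_pct <-
    ifelse(tab$m_loss > 0, 100 * tab$delta_m_loss / tab$m_loss, NA_real_)
  tab$negative_m_loss <- tab$m_loss < 0
  if (any(tab$negative_m_loss)) {
    warning("negative loss changing rate for ",
            sum(tab$negative_m_loss), " subject/level row(s)", call. = FALSE)
  }
  ord <- order(tab$subject_id, match(tab$level, bela_levels()))
  rownames(tab) <- NULL
  tab[ord, , drop = FALSE]
}

#' Full calibration run report
#'
#' Ties the statistical stage together: per-level calibrations of
#' visceral-fat area on the loss changing rate (each with R^2, p, SEE and
#' leave-one-out RMSE), the level-by-covariate correlation table, the
#' per-subject loss rates with repeatability, advisory outlier flags, and a
#' provenance manifest. Exclusions are explicit per-subject ids. No
#' multiple-testing adjustment is applied across the table; the report says
#' so.
#'
#' @param loss_rates Output of [loss_rate_table()].
#' @param areas Fat-areas data frame (schema of [read_areas_csv()]).
#' @param subjects Subjects data frame (schema of [read_subjects_csv()]).
#' @param exclude Subject ids excluded from every calibration fit.
#' @param manifest Optional provenance list carried into the report.
#' @return Object of class `bela_report`: `fits` (one [fit_calibration()]
#'   per level), `correlations`, `loss_rates`, `outlier_flags`, `warnings`,
#'   `manifest`, `notes`.
#' @export
calibration_report <- function(loss_rates, areas, subjects,
                               exclude = character(), manifest = NULL) {
  ids_known <- unique(loss_rates$subject_id)
  unmatched <- setdiff(unique(areas$subject_id), ids_known)
  if (length(unmatched)) {
    warning("fat-area subject id(s) without measurements: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  d <- merge(loss_rates, areas, by = c("subject_id", "level"))
  if (!nrow(d)) stop("no aligned subject/level rows", call. = FALSE)

  warns <- character()
  fits <- list()
  flags <- list()
  for (lv in bela_levels()) {
    dl <- d[d$level == lv, , drop = FALSE]
    if (nrow(dl) < 3L) next
    fits[[lv]] <- fit_calibration(dl$m_loss, dl$vf_area_cm2, dl$subject_id,
                                  exclude = intersect(exclude, dl$subject_id),
                                  level = lv)
    flags[[lv]] <- if (nrow(dl) >= 5L) {
      flag_outliers(dl$m_loss, dl$vf_area_cm2, dl$subject_id)
    } else character()
  }
  if (!length(fits)) stop("no level had >= 3 calibration points", call. = FALSE)

  cors <- withCallingHandlers(
    correlation_table(loss_rates, areas, subjects),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(loss_rates$negative_m_loss)) {
    warns <- c(warns, "negative loss changing rates present")
  }
  structure(list(
    fits = fits, correlations = cors, loss_rates = loss_rates,
    outlier_flags = flags, warnings = warns, manifest = manifest,
    notes = "p-values are per-cell two-sided tests; no multiple-testing adjustment applied"),
    class = "bela_report")
}

#' @export
print.bela_report <- function(x, ...) {
  cat("BELA calibration report\n")
  for (f in x$fits) print(f)
  cat("\nCorrelation table (R^2; p in parentheses):\n")
  wide <- x$correlations
  for (lv in unique(wide$level)) {
    sub <- wide[wide$level == lv, ]
    cat(sprintf("  %-8s %s\n", lv, paste(
      sprintf("%s=%.2f(%.3f)", sub$covariate, sub$r2, sub$p_value),
      collapse = " ")))
  }
  cat("\nMean relative repeatability: ",
      sprintf("%.1f %%", mean(x$loss_rates$relative_repeatability_pct,
                              na.rm = TRUE)), "\n", sep = "")
  if (length(x$warnings)) {
    cat("Warnings:\n  ", paste(x$warnings, collapse = "\n  "), "\n", sep = "")
  }
  cat("Note: ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Serialize a calibration report to JSON
#'
#' Full precision (display rounding is left to callers); the `lm` objects are
#' reduced to their coefficients.
#'
#' @param report A [calibration_report()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "bela_report"))
  fits <- lapply(report$fits, function(f) {
    f[c("level", "slope", "intercept", "r2", "p_value", "see", "loocv_rmse",
        "n_used", "excluded_ids")]
  })
  jsonlite::write_json(
    list(fits = fits, correlations = report$correlations,
         loss_rates = report$loss_rates,
         outlier_flags = report$outlier_flags,
         warnings = report$warnings, manifest = report$manifest,
         notes = report$notes),
    path, digits = NA, auto_unbox = TRUE, dataframe = "rows", null = "list")
  invisible(path)
}

#' Validate a cohort directory against the pipeline's invariants
#'
#' Re-reads the generated files and checks: the CSVs round-trip losslessly
#' into the declared schemas; re-evaluating the forward model on the stored
#' ground-truth compositions reproduces the stored noise-free voltage changes
#' and rates; and every subject has complete replicate coverage. Returns a
#' named logical vector of check results; any `FALSE` means the directory is
#' not a faithful pipeline fixture.
#'
#' @param dir Directory written by [write_cohort_files()].
#' @return Named logical vector of check outcomes.
#' @export
validate_cohort <- function(dir) {
  checks <- c(files_present = FALSE, schemas_parse = FALSE,
              truth_consistent = FALSE, replicates_complete = FALSE)
  files <- file.path(dir, c("measurements.csv", "areas.csv", "subjects.csv",
                            "ground_truth.json", "manifest.json"))
  checks["files_present"] <- all(file.exists(files))
  if (!checks["files_present"]) return(checks)

  parsed <- tryCatch({
    list(m = read_measurements_csv(files[1]), a = read_areas_csv(files[2]),
         s = read_subjects_csv(files[3]),
         gt = jsonlite::read_json(files[4], simplifyVector = TRUE),
         man = jsonlite::read_json(files[5], simplifyVector = TRUE))
  }, error = function(e) NULL)
  checks["schemas_parse"] <- !is.null(parsed)
  if (is.null(parsed)) return(checks)

  man <- parsed$man
  freqs <- frequency_pair(man$freqs$f_low, man$freqs$f_high)
  drive <- drive_config(man$gain)
  gt <- parsed$gt
  redone <- vapply(seq_len(nrow(gt)), function(i) {
    comp <- composition_section(gt$lean_interior_area[i], gt$vf_area[i],
                                gt$sf_area[i], gt$muscle_thickness[i],
                                gt$level[i])
    dv <- forward_voltage_change(comp, freqs, drive)
    m <- compute_m_loss(dv[["dv_high"]], dv[["dv_low"]], freqs)
    max(abs(c(dv[["dv_low"]] - gt$dv_low[i], dv[["dv_high"]] - gt$dv_high[i],
              m - gt$m_loss[i])))
  }, numeric(1))
  checks["truth_consistent"] <- all(redone < 1e-9)

  counts <- with(parsed$m,
                 table(subject_id, level, frequency_khz))
  checks["replicates_complete"] <- all(counts == man$n_replicates)
  checks
}
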