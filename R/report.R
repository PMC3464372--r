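# Report serialization: CSV tables plus a JSON summary, regenerable
# bit-identically from config + seed.

icc_long <- function(report) {
  sub <- cbind(scope = "control_subset", report$icc_subset$table)
  whole <- cbind(scope = "whole_sample", report$icc_whole)
  rbind(sub, whole)
}

#' Write a study report to disk
#'
#' Emits `volumes.csv` (per-subject measurements), `icc.csv` (control-subset
#' and whole-sample agreement coefficients), `group_tests.csv` (patient vs
#' control ANOVAs with adjusted p-values) and `report.json` (all summary
#' statistics). Figures, if wanted, should be regenerated from these tables.
#'
#' @param report A [run_study()] report.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$volumes, file.path(dir, "volumes.csv"),
                   row.names = FALSE)
  utils::write.csv(icc_long(report), file.path(dir, "icc.csv"),
                   row.names = FALSE)
  utils::write.csv(report$group_tests, file.path(dir, "group_tests.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report_summary(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Summarize a study report as a plain list (JSON-ready)
#'
#' @param report A [run_study()] report.
#' @return A list of summary statistics (group means, ICCs, tests).
#' @export
report_summary <- function(report) {
  stopifnot(inherits(report, "study_report"))
  lt <- report$lr_tests
  list(
    seed = report$config$seed,
    n_subjects = length(unique(report$volumes$subject)),
    group_summary = report$summary,
    icc = icc_long(report),
    icc_subset_subjects = report$icc_subset$subjects,
    left_right = lapply(lt, function(t) {
      list(f = t$statistic, df = t$df, p = t$p_value)
    }),
    asymmetry_test = list(f = report$asymmetry$test$statistic,
                          df = report$asymmetry$test$df,
                          p = report$asymmetry$test$p_value),
    group_tests = report$group_tests
  )
}
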