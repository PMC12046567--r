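#' Write the three input tables of a synthetic cohort to CSV
#'
#' Emits the dialects the pipeline reads back: `visits.csv`
#' (`subject,visit,age,diagnosis,<covariates>`), `selfreport.csv`
#' (`subject,age,sr_tst,sr_bed,sr_wake`), and `pathways.csv`
#' (`subject,pathway,mci_onset_age,dementia_onset_age` — the generating
#' truth, useful for recovery checks). Epoch-level activity, when simulated,
#' is written separately with [write_epoch_csv()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort_csvs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sr_cols <- c("subject", "age", "sr_tst", "sr_bed", "sr_wake")
  utils::write.csv(cohort$visits[setdiff(names(cohort$visits), c("sr_tst", "sr_bed", "sr_wake"))],
                   file.path(dir, "visits.csv"), row.names = FALSE)
  utils::write.csv(cohort$visits[sr_cols], file.path(dir, "selfreport.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "pathways.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a visit table
#'
#' @param path CSV with at least `subject,age,diagnosis`.
#' @return Data.frame ordered by subject and age.
#' @export
read_visit_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "age", "diagnosis") %in% names(df)))
  df[order(df$subject, df$age), ]
}

#' Write a long-format contrast table
#'
#' @param contrasts Output of [run_benchmark_grid()].
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_contrast_csv <- function(contrasts, path) {
  utils::write.csv(contrasts, path, row.names = FALSE)
  invisible(path)
}
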