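#' Assign a cognitive-aging pathway from an annual diagnosis sequence
#'
#' Classifies a subject's ordered visit diagnoses into one of three pathways:
#' `"dementia"` if any visit carries a dementia diagnosis (onset = age at the
#' first such visit); otherwise `"stableMCI"` if some pair of consecutive
#' visits are both MCI (a single MCI year reverts often enough that two
#' consecutive diagnoses are required to index stable impairment); otherwise
#' `"normal"`. MCI onset is the age at the first visit of the earliest
#' consecutive-MCI pair; on the dementia pathway it is recorded only when such
#' a pair precedes the first dementia visit (an MCI history is not required).
#'
#' Visits are "consecutive" when separated by at most `gap_max_yr` years
#' (default 1.5, accommodating annual visits with scheduling jitter); larger
#' gaps break consecutiveness. A lone MCI diagnosis at the final visit of an
#' otherwise-normal subject is classified normal by the literal rule but
#' flagged (`censored_mci`), since follow-up ended before the rule could
#' resolve.
#'
#' @param ages Numeric vector of visit ages (years), increasing.
#' @param diagnoses Character vector in `{"NCI", "MCI", "dementia"}`, same
#'   length as `ages`.
#' @param gap_max_yr Maximum visit gap (years) still counted as consecutive.
#' @param onset_visit Which visit of the earliest qualifying MCI pair defines
#'   MCI onset: `"first"` (default) or `"second"`.
#' @return A list of class `pathway_label`: `pathway`, `mci_onset_age`,
#'   `dementia_onset_age`, `censored_mci`.
#' @export
assign_pathway <- function(ages, diagnoses, gap_max_yr = 1.5,
                           onset_visit = c("first", "second")) {
  onset_visit <- match.arg(onset_visit)
  if (length(ages) == 0) stop("at least one visit is required")
  if (length(ages) != length(diagnoses)) stop("ages and diagnoses lengths differ")
  bad <- setdiff(unique(diagnoses), c("NCI", "MCI", "dementia"))
  if (length(bad)) stop("unknown diagnosis value(s): ", paste(bad, collapse = ", "))
  o <- order(ages)
  ages <- ages[o]; diagnoses <- diagnoses[o]
  n <- length(ages)

  dem_idx <- which(diagnoses == "dementia")
  dem_onset <- if (length(dem_idx)) ages[dem_idx[1]] else NA_real_

  # earliest consecutive-MCI pair (optionally restricted to before dementia)
  mci_pair_onset <- function(last_idx) {
    if (last_idx < 2) return(NA_real_)
    for (i in seq_len(last_idx - 1)) {
      if (diagnoses[i] == "MCI" && diagnoses[i + 1] == "MCI" &&
          (ages[i + 1] - ages[i]) <= gap_max_yr) {
        return(if (onset_visit == "first") ages[i] else ages[i + 1])
      }
    }
    NA_real_
  }

  if (length(dem_idx)) {
    # the qualifying pair must lie fully before the first dementia visit
    lab <- list(pathway = "dementia",
                mci_onset_age = mci_pair_onset(dem_idx[1] - 1),
                dementia_onset_age = dem_onset,
                censored_mci = FALSE)
  } else {
    mci_onset <- mci_pair_onset(n)
    if (!is.na(mci_onset)) {
      lab <- list(pathway = "stableMCI", mci_onset_age = mci_onset,
                  dementia_onset_age = NA_real_, censored_mci = FALSE)
    } else {
      lab <- list(pathway = "normal", mci_onset_age = NA_real_,
                  dementia_onset_age = NA_real_,
                  censored_mci = diagnoses[n] == "MCI")
    }
  }
  structure(lab, class = "pathway_label")
}

#' @export
print.pathway_label <- function(x, ...) {
  cat(sprintf("<pathway_label> %s (MCI onset %s, dementia onset %s)%s\n",
              x$pathway,
              ifelse(is.na(x$mci_onset_age), "-", format(x$mci_onset_age)),
              ifelse(is.na(x$dementia_onset_age), "-", format(x$dementia_onset_age)),
              if (isTRUE(x$censored_mci)) " [censored lone MCI at end]" else ""))
  invisible(x)
}

#' Assign pathways for every subject in a visit table
#'
#' @param visits Data.frame with columns `subject`, `age`, `diagnosis`.
#' @param ... Passed to [assign_pathway()].
#' @return Data.frame with one row per subject: `subject`, `pathway`,
#'   `mci_onset_age`, `dementia_onset_age`, `censored_mci`.
#' @export
assign_pathways <- function(visits, ...) {
  stopifnot(all(c("subject", "age", "diagnosis") %in% names(visits)))
  out <- lapply(split(visits, visits$subject), function(d) {
    lab <- assign_pathway(d$age, d$diagnosis, ...)
    data.frame(subject = d$subject[1], pathway = lab$pathway,
               mci_onset_age = lab$mci_onset_age,
               dementia_onset_age = lab$dementia_onset_age,
               censored_mci = lab$censored_mci)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
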