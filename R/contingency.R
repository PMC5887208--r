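#' Count (drug, stratum, adverse event) triples
#'
#' Builds, for every candidate triple (drug A, primary-disease stratum B,
#' adverse event C), the eight-cell count vector shared by both detectors:
#'
#' \describe{
#'   \item{n_AB1}{reports containing A, in B, with C}
#'   \item{n_AB2}{reports containing A, in B, without C}
#'   \item{n_AB_plus}{n_AB1 + n_AB2 (all A-exposed reports in B)}
#'   \item{n_B1, n_B2, n_B_plus}{the same three cells for B-reports without A}
#'   \item{n_plus1}{reports with C in the whole dataset}
#'   \item{n_plusplus}{all reports in the whole dataset}
#' }
#'
#' The counting unit is the report: a report listing a drug or event twice
#' contributes once to any cell. The association-rule baseline `n_plus1 /
#' n_plusplus` spans the entire dataset while the PRR comparator cells
#' `n_B1 / n_B_plus` are restricted to stratum B; both live in the same row
#' so each statistic uses its own denominator.
#'
#' Candidate generation is apriori-pruned at `min_count`: a drug (or event)
#' whose own support inside the stratum is below `min_count` can never head
#' a triple with `n_AB1 >= min_count`, so its co-occurrences are never
#' scanned.
#'
#' @param dataset an [srs_dataset()].
#' @param stratum_members named list of case-id vectors, as returned by
#'   [annotate_strata()].
#' @param min_count minimum `n_AB1` (rule count) for a triple to be emitted;
#'   must be >= 1.
#' @return a data.frame of class `triple_counts` with columns `drug`,
#'   `stratum`, `event` and the eight counts.
#' @export
count_triples <- function(dataset, stratum_members, min_count = 1L) {
  stopifnot(inherits(dataset, "srs_dataset"))
  min_count <- as.integer(min_count)
  if (is.na(min_count) || min_count < 1L) stop("min_count must be >= 1")
  if (length(dataset$case_ids) == 0L) {
    stop("validation error: empty dataset (no reports)")
  }
  if (is.null(names(stratum_members)) && length(stratum_members)) {
    stop("stratum_members must be a named list of case-id vectors")
  }

  n_pp <- length(dataset$case_ids)
  ev_total <- dataset$events[, .(n_plus1 = .N), by = .(event = item)]

  per_stratum <- lapply(names(stratum_members), function(b) {
    S <- unique(stratum_members[[b]])
    nB_total <- length(S)
    if (nB_total < min_count) return(NULL)  # apriori: support({B}) too low
    dS <- dataset$drugs[case_id %chin% S]
    eS <- dataset$events[case_id %chin% S]
    # apriori pruning of the {A,B} and {B,C} sub-itemsets
    nA <- dS[, .(n_AB_plus = .N), by = .(drug = item)][n_AB_plus >= min_count]
    nC <- eS[, .(nC_B = .N), by = .(event = item)][nC_B >= min_count]
    if (!nrow(nA) || !nrow(nC)) return(NULL)
    dS <- dS[item %chin% nA$drug]
    eS <- eS[item %chin% nC$event]
    co <- merge(dS[, .(case_id, drug = item)],
                eS[, .(case_id, event = item)],
                by = "case_id", allow.cartesian = TRUE)
    if (!nrow(co)) return(NULL)
    tr <- co[, .(n_AB1 = .N), by = .(drug, event)][n_AB1 >= min_count]
    if (!nrow(tr)) return(NULL)
    tr <- merge(tr, nA, by = "drug")
    tr <- merge(tr, nC, by = "event")
    tr[, `:=`(
      stratum = b,
      n_AB2 = n_AB_plus - n_AB1,
      n_B1 = nC_B - n_AB1,
      n_B_plus = nB_total - n_AB_plus
    )]
    tr[, n_B2 := n_B_plus - n_B1]
    tr[, nC_B := NULL]
    tr
  })
  out <- rbindlist(per_stratum)
  if (is.null(out) || !nrow(out)) {
    out <- data.table(drug = character(), event = character(), n_AB1 = integer(),
                      n_AB_plus = integer(), stratum = character(),
                      n_AB2 = integer(), n_B1 = integer(),
                      n_B_plus = integer(), n_B2 = integer())
  }
  out <- merge(out, ev_total, by = "event", all.x = TRUE)
  out[, n_plusplus := n_pp]
  setcolorder(out, c("drug", "stratum", "event",
                     "n_AB1", "n_AB2", "n_AB_plus",
                     "n_B1", "n_B2", "n_B_plus", "n_plus1", "n_plusplus"))
  setorder(out, stratum, drug, event)
  validate_triple_counts(out)
  setDF(out)
  class(out) <- c("triple_counts", "data.frame")
  out
}

# cell-conservation invariants, asserted on every emitted triple
validate_triple_counts <- function(x) {
  with(x, {
    stopifnot(all(n_AB1 + n_AB2 == n_AB_plus),
              all(n_B1 + n_B2 == n_B_plus),
              all(n_AB1 >= 0), all(n_B1 >= 0), all(n_B2 >= 0),
              all(n_AB1 <= n_plus1), all(n_plus1 <= n_plusplus))
  })
  invisible(x)
}

#' Triple identifier strings
#'
#' Canonical `drug|stratum|event` keys used as set elements by the
#' evaluation module.
#'
#' @param counts a `triple_counts` or rules data.frame with `drug`,
#'   `stratum`, `event` columns.
#' @export
triple_id <- function(counts) {
  paste(counts$drug, counts$stratum, counts$event, sep = "|")
}
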