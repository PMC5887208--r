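# Brute-force oracles, independent of the package's counting path.
# Reports are plain lists of character sets; all counting below is naive
# enumeration over those lists.

# draw a random report list with base R only (independent of simulate_srs)
random_reports <- function(n, n_drugs = 6, n_hists = 3, n_events = 6,
                           p_drug = 0.25, p_hist = 0.4, p_event = 0.25) {
  drugs <- sprintf("D%d", seq_len(n_drugs))
  hists <- sprintf("H%d", seq_len(n_hists))
  events <- sprintf("E%d", seq_len(n_events))
  lapply(seq_len(n), function(i) {
    list(drugs = drugs[runif(n_drugs) < p_drug],
         hists = hists[runif(n_hists) < p_hist],
         events = events[runif(n_events) < p_event])
  })
}

reports_to_dataset <- function(reports, ids = sprintf("R%04d", seq_along(reports))) {
  pair <- function(field) {
    do.call(rbind, lapply(seq_along(reports), function(i) {
      it <- reports[[i]][[field]]
      if (!length(it)) NULL else data.frame(case_id = ids[i], item = it)
    }))
  }
  srs_dataset(ids, drugs = pair("drugs"), hists = pair("hists"),
              events = pair("events"))
}

# exhaustive (A, B, C) enumeration: every drug x stratum x event, no pruning
oracle_counts <- function(reports, strata_terms, min_count = 1L) {
  all_drugs <- sort(unique(unlist(lapply(reports, `[[`, "drugs"))))
  all_events <- sort(unique(unlist(lapply(reports, `[[`, "events"))))
  n_pp <- length(reports)
  rows <- list()
  for (b in names(strata_terms)) {
    member <- vapply(reports, function(r) {
      length(intersect(r$hists, strata_terms[[b]])) > 0
    }, logical(1))
    for (A in all_drugs) {
      hasA <- vapply(reports, function(r) A %in% r$drugs, logical(1))
      for (C in all_events) {
        hasC <- vapply(reports, function(r) C %in% r$events, logical(1))
        n_AB1 <- sum(member & hasA & hasC)
        if (n_AB1 < min_count) next
        rows[[length(rows) + 1L]] <- data.frame(
          drug = A, stratum = b, event = C,
          n_AB1 = n_AB1,
          n_AB2 = sum(member & hasA & !hasC),
          n_AB_plus = sum(member & hasA),
          n_B1 = sum(member & !hasA & hasC),
          n_B2 = sum(member & !hasA & !hasC),
          n_B_plus = sum(member & !hasA),
          n_plus1 = sum(hasC), n_plusplus = n_pp,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(drug = character(), stratum = character(), event = character())
  out[order(out$stratum, out$drug, out$event), , drop = FALSE]
}

# brute-force rule mining: oracle counts + direct formulas + criteria
oracle_mine <- function(reports, strata_terms, min_count = 3,
                        min_lift = 1, min_conviction = 1) {
  oc <- oracle_counts(reports, strata_terms, min_count = 1L)
  if (!nrow(oc)) return(oc)
  oc$lift <- (oc$n_AB1 / oc$n_AB_plus) / (oc$n_plus1 / oc$n_plusplus)
  conf <- oc$n_AB1 / oc$n_AB_plus
  oc$conviction <- ifelse(conf == 1, Inf,
                          (1 - oc$n_plus1 / oc$n_plusplus) / (1 - conf))
  oc[oc$n_AB1 >= min_count & oc$lift > min_lift &
       oc$conviction > min_conviction, , drop = FALSE]
}

# independent continuity-corrected chi-square (NA where chisq.test cannot run)
oracle_chi2 <- function(a, b, c_, d) {
  mapply(function(a, b, c_, d) {
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) {
      return(NA_real_)
    }
    unname(suppressWarnings(
      stats::chisq.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                        correct = TRUE)$statistic))
  }, a, b, c_, d)
}

# Mann-Whitney pairwise-concordance AUC with ties counted 1/2
oracle_auc <- function(scores_pos, scores_neg) {
  gt <- outer(scores_pos, scores_neg, `>`)
  eq <- outer(scores_pos, scores_neg, `==`)
  mean(gt + 0.5 * eq)
}

toy_paths <- function() {
  p <- vapply(c(demo = "toy_demo.csv", drug = "toy_drug.csv",
                reac = "toy_reac.csv", hist = "toy_hist.csv",
                strata = "toy_strata.yaml"),
              function(f) system.file("extdata", f, package = "adescreen"),
              character(1))
  stopifnot(all(nzchar(p)))
  p
}
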