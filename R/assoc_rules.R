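#' Association-rule lift for A ∩ B → C
#'
#' Lift is the confidence of the rule divided by the support of the
#' consequent: `(n_AB1/n_AB_plus) / (n_plus1/n_plusplus)`. Lift 1 means the
#' antecedent (drug within stratum) and the adverse event are independent;
#' lift above 1 means the event is over-represented among exposed stratum
#' reports relative to the whole database.
#'
#' @param counts a `triple_counts` data.frame (or any data.frame with the
#'   count columns); vectorized over rows.
#' @return numeric vector of non-negative lift values.
#' @export
ar_lift <- function(counts) {
  if (any(counts$n_AB_plus < 1L)) stop("lift undefined: n_AB_plus < 1")
  if (any(counts$n_plus1 < 1L)) {
    stop("undefined statistic: adverse event never observed (n_plus1 = 0)")
  }
  (counts$n_AB1 / counts$n_AB_plus) / (counts$n_plus1 / counts$n_plusplus)
}

#' Association-rule conviction for A ∩ B → C
#'
#' Conviction is `(1 - support(C)) / (1 - confidence)`. It is 1 under
#' independence, grows as the rule's predictions fail less often than
#' chance, and is `+Inf` when confidence is exactly 1 (the rule is never
#' wrong in the data).
#'
#' @inheritParams ar_lift
#' @return numeric vector; positive, possibly `Inf`.
#' @export
ar_conviction <- function(counts) {
  if (any(counts$n_AB_plus < 1L)) stop("conviction undefined: n_AB_plus < 1")
  if (any(counts$n_plus1 < 1L)) {
    stop("undefined statistic: adverse event never observed (n_plus1 = 0)")
  }
  support_C <- counts$n_plus1 / counts$n_plusplus
  confidence <- counts$n_AB1 / counts$n_AB_plus
  out <- (1 - support_C) / (1 - confidence)
  out[confidence == 1] <- Inf
  out
}

# full AR statistics block for a counts table
ar_metrics <- function(counts) {
  data.frame(
    support_C = counts$n_plus1 / counts$n_plusplus,
    confidence = counts$n_AB1 / counts$n_AB_plus,
    lift = ar_lift(counts),
    conviction = ar_conviction(counts),
    rule_count = counts$n_AB1
  )
}

#' Association-rule signal flag
#'
#' The screening criteria: rule count (`n_AB1`) at least `min_count`
#' (non-strict), lift strictly above `min_lift`, and conviction strictly
#' above `min_conviction`. With the defaults these are the criteria
#' "rule count >= 3", "lift > 1", "conviction > 1"; lift exactly 1 is not a
#' signal.
#'
#' @param rule_count,lift,conviction numeric vectors (recycled together).
#' @param min_count,min_lift,min_conviction thresholds.
#' @return logical vector.
#' @export
ar_signal <- function(rule_count, lift, conviction,
                      min_count = 3, min_lift = 1, min_conviction = 1) {
  rule_count >= min_count & lift > min_lift & conviction > min_conviction
}

#' Mine association-rule signals
#'
#' Enumerates candidate triples under apriori pruning (see
#' [count_triples()]) and emits exactly those satisfying the AR detection
#' criteria.
#'
#' @param dataset an [srs_dataset()].
#' @param strata strata accepted by [annotate_strata()], or a precomputed
#'   stratum-membership list.
#' @param min_count minimum rule count (`n_AB1`), non-strict.
#' @param min_lift,min_conviction strict lower thresholds.
#' @return data.frame with the triple keys, all eight counts, and the AR
#'   statistics, one row per emitted rule.
#' @export
mine_rules <- function(dataset, strata, min_count = 3L,
                       min_lift = 1, min_conviction = 1) {
  members <- if (is.list(strata) && length(strata) &&
                 is.character(strata[[1]]) && !is.null(names(strata)) &&
                 all(unlist(strata) %in% dataset$case_ids)) {
    strata
  } else {
    annotate_strata(dataset, strata)
  }
  counts <- count_triples(dataset, members, min_count = min_count)
  res <- cbind(as.data.frame(counts), ar_metrics(counts))
  res[ar_signal(res$rule_count, res$lift, res$conviction,
                min_count, min_lift, min_conviction), , drop = FALSE]
}
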