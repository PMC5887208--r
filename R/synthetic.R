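#' Configuration for the synthetic SRS generator
#'
#' Describes a synthetic spontaneous-report world: per-report inclusion
#' probabilities for every drug and history term, baseline per-report
#' probabilities for every adverse event, and a set of injected
#' (drug, history, event) triples whose event probability is multiplied by
#' a relative risk when the report carries both the drug and the history
#' term. Everything else is independent — the minimal structure both
#' detectors assume.
#'
#' @param n_reports number of reports to draw.
#' @param drug_catalog named numeric vector: drug name -> marginal
#'   inclusion probability.
#' @param hist_catalog named numeric vector: history (primary disease)
#'   term -> prevalence.
#' @param event_catalog named numeric vector: adverse event preferred
#'   term -> baseline per-report probability.
#' @param injected_effects data.frame with columns `drug`, `hist`, `event`,
#'   `rr` (relative risk, >= 1); may have zero rows.
#' @param seed integer RNG seed; the same config always yields the same
#'   dataset.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_reports, drug_catalog, hist_catalog, event_catalog,
                       injected_effects = NULL, seed = 1L) {
  chk_probs <- function(p, what) {
    if (is.null(names(p)) || any(names(p) == "") || anyDuplicated(names(p))) {
      stop("validation error: ", what, " must be uniquely named")
    }
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop("validation error: ", what, " probabilities must lie in [0, 1]")
    }
  }
  chk_probs(drug_catalog, "drug_catalog")
  chk_probs(hist_catalog, "hist_catalog")
  chk_probs(event_catalog, "event_catalog")
  if (is.null(injected_effects)) {
    injected_effects <- data.frame(drug = character(), hist = character(),
                                   event = character(), rr = numeric())
  }
  injected_effects <- as.data.frame(injected_effects)
  stopifnot(all(c("drug", "hist", "event", "rr") %in% names(injected_effects)))
  if (nrow(injected_effects)) {
    if (!all(injected_effects$drug %in% names(drug_catalog)) ||
        !all(injected_effects$hist %in% names(hist_catalog)) ||
        !all(injected_effects$event %in% names(event_catalog))) {
      stop("validation error: injected effect references an unknown catalog item")
    }
    if (any(injected_effects$rr < 1)) {
      stop("validation error: relative risks must be >= 1")
    }
    eff_p <- injected_effects$rr * event_catalog[injected_effects$event]
    if (any(eff_p > 1)) {
      stop("validation error: rr * baseline exceeds 1 for ",
           sum(eff_p > 1), " injected triple(s)")
    }
    if (anyDuplicated(injected_effects[, c("drug", "hist", "event")])) {
      stop("validation error: duplicate injected triples")
    }
  }
  n_reports <- as.integer(n_reports)
  if (is.na(n_reports) || n_reports < 0L) stop("n_reports must be >= 0")
  structure(list(n_reports = n_reports, drug_catalog = drug_catalog,
                 hist_catalog = hist_catalog, event_catalog = event_catalog,
                 injected_effects = injected_effects, seed = as.integer(seed)),
            class = "sim_config")
}

#' Packaged default simulation: a 1/10-scale JADER-like world
#'
#' Mirrors the scale ratios of a deduplicated, oral-route national SRS
#' extract at one tenth size: 18,000 reports; two primary-disease strata
#' ("kidney injury" at 10% prevalence, "liver injury" at 12.5%, matching
#' the kidney/liver case fractions of such extracts) plus three common
#' comorbidity terms as background noise; 40 drugs and 50 adverse-event
#' preferred terms with long-tailed (log-spaced) marginal frequencies, as
#' SRS marginals are heavily skewed; and 5% of the drug x disease x event
#' triples injected with relative risks drawn uniformly from the integers
#' 2..10.
#'
#' @param seed integer seed; drives both the choice of injected triples and
#'   the report sampling.
#' @return a [sim_config()].
#' @export
default_sim_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  drugs <- setNames(exp(seq(log(0.002), log(0.10), length.out = 40)),
                    sprintf("DRUG%02d", 1:40))
  hists <- c("kidney injury" = 0.100, "liver injury" = 0.125,
             "hypertension" = 0.20, "diabetes mellitus" = 0.15,
             "dyslipidaemia" = 0.10)
  events <- setNames(exp(seq(log(0.001), log(0.020), length.out = 50)),
                     sprintf("AE%02d", 1:50))
  strata_terms <- c("kidney injury", "liver injury")
  all_triples <- expand.grid(drug = names(drugs), hist = strata_terms,
                             event = names(events),
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_inject <- round(0.05 * nrow(all_triples))
  old <- globalenv()$.Random.seed
  set.seed(seed)
  pick <- sample.int(nrow(all_triples), n_inject)
  inj <- all_triples[pick, ]
  inj$rr <- sample(2:10, n_inject, replace = TRUE)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  sim_config(n_reports = 18000L, drug_catalog = drugs, hist_catalog = hists,
             event_catalog = events, injected_effects = inj, seed = seed)
}

#' Default stratum definitions matching [default_sim_config()]
#' @export
default_strata <- function() {
  list("kidney injury" = stratum_definition("kidney injury", "kidney injury"),
       "liver injury" = stratum_definition("liver injury", "liver injury"))
}

#' Generate a synthetic SRS dataset
#'
#' Draws each report's drugs and history terms independently from the
#' catalog probabilities; each adverse event is then drawn with probability
#' `baseline * rr` if the report carries an injected triple's drug and
#' history term (the largest applicable `rr` wins if several triples share
#' the event), else `baseline`. The injected triples are returned alongside
#' the data as ground truth, augmented with each triple's expected rule
#' count under the configuration, so tests never reverse-engineer the
#' generator.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (an [srs_dataset()]) and `truth` (the
#'   injected-effects data.frame plus `expected_n_AB1`).
#' @export
simulate_srs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_reports
  dc <- config$drug_catalog; hc <- config$hist_catalog; ec <- config$event_catalog
  inj <- config$injected_effects
  truth <- inj
  if (nrow(truth)) {
    truth$expected_n_AB1 <- config$n_reports * dc[truth$drug] * hc[truth$hist] *
      pmin(1, truth$rr * ec[truth$event])
    rownames(truth) <- NULL
  } else {
    truth$expected_n_AB1 <- numeric()
  }
  case_ids <- if (n > 0L) sprintf("C%06d", seq_len(n)) else character()
  if (n == 0L) {
    return(list(dataset = srs_dataset(case_ids), truth = truth))
  }

  old_seed <- globalenv()$.Random.seed
  set.seed(config$seed)
  draw <- function(p) {
    m <- matrix(runif(n * length(p)), n, length(p)) <
      matrix(p, n, length(p), byrow = TRUE)
    colnames(m) <- names(p)
    m
  }
  Md <- draw(dc)
  Mh <- draw(hc)
  P <- matrix(ec, n, length(ec), byrow = TRUE, dimnames = list(NULL, names(ec)))
  if (nrow(inj)) {
    for (i in seq_len(nrow(inj))) {
      hit <- Md[, inj$drug[i]] & Mh[, inj$hist[i]]
      j <- inj$event[i]
      P[hit, j] <- pmax(P[hit, j], pmin(1, ec[[j]] * inj$rr[i]))
    }
  }
  Me <- matrix(runif(n * length(ec)), n, length(ec)) < P
  colnames(Me) <- names(ec)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  long_pairs <- function(m) {
    w <- which(m, arr.ind = TRUE)
    data.table(case_id = case_ids[w[, 1L]], item = colnames(m)[w[, 2L]])
  }
  dataset <- srs_dataset(case_ids,
                         drugs = long_pairs(Md),
                         hists = long_pairs(Mh),
                         events = long_pairs(Me),
                         provenance = sprintf(
                           "simulated: n=%d, %d drugs, %d hist terms, %d events, %d injected triples, seed=%d",
                           n, length(dc), length(hc), length(ec), nrow(inj), config$seed))
  list(dataset = dataset, truth = truth)
}

#' Export an SRS dataset as JADER-style four tables
#'
#' Writes DEMO, DRUG, REAC and HIST CSV files that round-trip through
#' [load_dataset()] (with the default [srs_config()]) to an identical
#' dataset. Demographic fields carry a placeholder since the canonical
#' dataset does not model them; every drug row is exported as an oral-route
#' suspect drug.
#'
#' @param dataset an [srs_dataset()]; must be non-empty.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the four file paths (named demo/drug/reac/hist).
#' @export
export_jader_tables <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "srs_dataset"))
  if (length(dataset$case_ids) == 0L) stop("cannot export an empty dataset")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create directory ", out_dir)
  paths <- file.path(out_dir, c(demo = "demo.csv", drug = "drug.csv",
                                reac = "reac.csv", hist = "hist.csv"))
  names(paths) <- c("demo", "drug", "reac", "hist")
  fwrite(data.table(case_id = dataset$case_ids, sex = "unknown", age = ""),
         paths[["demo"]])
  fwrite(dataset$drugs[, .(case_id, drug = item, role = "suspect", route = "oral")],
         paths[["drug"]])
  fwrite(dataset$events[, .(case_id, event = item)], paths[["reac"]])
  fwrite(dataset$hists[, .(case_id, hist = item)], paths[["hist"]])
  invisible(paths)
}
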