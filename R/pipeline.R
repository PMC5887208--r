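#' Screen all candidate triples with both detectors
#'
#' The core screening table: every candidate (drug, stratum, event) triple
#' with `n_AB1 >= universe_min_count`, its eight counts, the
#' association-rule statistics (support, confidence, lift, conviction) with
#' the AR signal flag, and the stratified PRR statistics (PRR, Yates
#' chi-squared, signal intensity) with the MHRA-style PRR signal flag.
#' Every flag is recomputable from the statistic columns of its own row.
#'
#' @param dataset an [srs_dataset()].
#' @param strata strata accepted by [annotate_strata()].
#' @param min_count,min_lift,min_conviction AR detection thresholds
#'   (count non-strict, lift/conviction strict).
#' @param min_prr,min_chi2 PRR detection thresholds (non-strict, together
#'   with the same `min_count`).
#' @param universe_min_count minimum `n_AB1` for a triple to enter the
#'   candidate universe (default 1).
#' @return data.frame of class `screen_result`.
#' @export
screen_triples <- function(dataset, strata,
                           min_count = 3, min_lift = 1, min_conviction = 1,
                           min_prr = 2, min_chi2 = 4,
                           universe_min_count = 1L) {
  members <- annotate_strata(dataset, strata)
  counts <- count_triples(dataset, members, min_count = universe_min_count)
  res <- cbind(as.data.frame(counts), ar_metrics(counts))
  pm <- prr_metrics(counts)
  res$prr <- pm$prr
  res$chi2 <- pm$chi2
  res$intensity <- pm$intensity
  res$ar_signal <- ar_signal(res$rule_count, res$lift, res$conviction,
                             min_count, min_lift, min_conviction)
  res$prr_signal <- suppressWarnings(
    prr_signal(res$rule_count, res$prr, res$chi2, min_count, min_prr, min_chi2))
  attr(res, "thresholds") <- list(min_count = min_count, min_lift = min_lift,
                                  min_conviction = min_conviction,
                                  min_prr = min_prr, min_chi2 = min_chi2,
                                  universe_min_count = universe_min_count)
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Run configuration for the end-to-end pipeline
#'
#' Bundles the input source (four JADER-style tables or a simulation
#' configuration), the stratum definitions, and all detection and
#' evaluation thresholds. Threshold defaults are the published detection
#' criteria: rule count >= 3, lift > 1, conviction > 1 for the AR
#' detector; PRR >= 2 and chi-squared >= 4 (with the same count gate) for
#' the PRR detector.
#'
#' @param demo,drug,reac,hist paths to the four tables (ignored when
#'   `sim` is given).
#' @param sim a [sim_config()], or `TRUE` for [default_sim_config()].
#' @param strata strata accepted by [annotate_strata()]; defaults to
#'   [default_strata()] when simulating.
#' @param io an [srs_config()] for table reading.
#' @param min_count,min_lift,min_conviction,min_prr,min_chi2 detector
#'   thresholds.
#' @param universe_min_count candidate-universe rule-count floor.
#' @param roc_score ROC ranking score, `"lift"` or `"conviction"`.
#' @param out_dir optional output directory; when set, [run_screen()]
#'   writes the rules table, evaluation report, ROC points and provenance
#'   there.
#' @param seed seed applied to the simulation source.
#' @export
run_config <- function(demo = NULL, drug = NULL, reac = NULL, hist = NULL,
                       sim = NULL, strata = NULL, io = srs_config(),
                       min_count = 3, min_lift = 1, min_conviction = 1,
                       min_prr = 2, min_chi2 = 4,
                       universe_min_count = 1L,
                       roc_score = "lift",
                       out_dir = NULL, seed = 1L) {
  if (isTRUE(sim)) sim <- default_sim_config(seed)
  if (is.null(sim) && (is.null(demo) || is.null(drug) ||
                       is.null(reac) || is.null(hist))) {
    stop("run_config needs either all four table paths or a simulation config")
  }
  if (is.null(strata)) {
    if (is.null(sim)) stop("strata definitions are required when loading tables")
    strata <- default_strata()
  }
  structure(list(demo = demo, drug = drug, reac = reac, hist = hist,
                 sim = sim, strata = strata, io = io,
                 min_count = min_count, min_lift = min_lift,
                 min_conviction = min_conviction, min_prr = min_prr,
                 min_chi2 = min_chi2, universe_min_count = universe_min_count,
                 roc_score = roc_score, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

eval_report_list <- function(evaluation) {
  lapply(evaluation, function(e) {
    list(
      n_universe = e$n_universe,
      confusion = unclass(e$confusion),
      auc = if (!is.null(e$roc)) e$roc$auc else NA_real_,
      regression = if (!is.null(e$fit)) unclass(e$fit) else NULL
    )
  })
}

#' Run the full screening pipeline
#'
#' Loads or simulates the dataset, screens every candidate triple with
#' both detectors, evaluates their head-to-head agreement per stratum, and
#' (when `config$out_dir` is set) writes `rules.csv`, `evaluation.json`,
#' `roc_points.csv` and `provenance.json`. On error, partially written
#' outputs are removed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `dataset`, `rules`, `evaluation`, and
#'   `truth` (simulation ground truth, `NULL` for file input).
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "run_config"))
  written <- character()
  on_fail <- function(stage, e) {
    unlink(written)
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  }

  truth <- NULL
  dataset <- tryCatch({
    if (!is.null(config$sim)) {
      simc <- config$sim
      simc$seed <- config$seed
      s <- simulate_srs(simc)
      truth <- s$truth
      s$dataset
    } else {
      load_dataset(config$demo, config$drug, config$reac, config$hist, config$io)
    }
  }, error = function(e) on_fail("load", e))

  rules <- tryCatch(
    screen_triples(dataset, config$strata,
                   min_count = config$min_count, min_lift = config$min_lift,
                   min_conviction = config$min_conviction,
                   min_prr = config$min_prr, min_chi2 = config$min_chi2,
                   universe_min_count = config$universe_min_count),
    error = function(e) on_fail("screen", e))

  evaluation <- tryCatch(
    evaluate_detectors(rules, roc_score = config$roc_score,
                       count_gate = config$min_count),
    error = function(e) on_fail("evaluate", e))

  if (!is.null(config$out_dir)) {
    tryCatch({
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      p_rules <- file.path(config$out_dir, "rules.csv")
      fwrite(as.data.table(as.data.frame(rules)), p_rules)
      written <- c(written, p_rules)

      p_eval <- file.path(config$out_dir, "evaluation.json")
      jsonlite::write_json(eval_report_list(evaluation), p_eval,
                           auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", pretty = TRUE)
      written <- c(written, p_eval)

      roc_pts <- rbindlist(lapply(names(evaluation), function(b) {
        r <- evaluation[[b]]$roc
        if (is.null(r)) return(NULL)
        data.table(stratum = b, fpr = r$points$fpr, tpr = r$points$tpr)
      }))
      p_roc <- file.path(config$out_dir, "roc_points.csv")
      fwrite(if (nrow(roc_pts)) roc_pts else
               data.table(stratum = character(), fpr = numeric(), tpr = numeric()),
             p_roc)
      written <- c(written, p_roc)

      prov <- list(
        seed = config$seed,
        source = if (is.null(config$sim)) "tables" else "simulation",
        n_reports = n_reports(dataset),
        n_triples = nrow(rules),
        thresholds = attr(rules, "thresholds"),
        dataset_provenance = dataset$provenance
      )
      p_prov <- file.path(config$out_dir, "provenance.json")
      jsonlite::write_json(prov, p_prov, auto_unbox = TRUE, pretty = TRUE)
      written <- c(written, p_prov)
      if (!is.null(truth)) {
        p_truth <- file.path(config$out_dir, "truth.csv")
        fwrite(as.data.table(truth), p_truth)
        written <- c(written, p_truth)
      }
    }, error = function(e) on_fail("write", e))
  }

  invisible(list(dataset = dataset, rules = rules,
                 evaluation = evaluation, truth = truth))
}
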