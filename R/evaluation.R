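#' Confusion metrics of one detector against another
#'
#' Cross-tabulates a predicted signal set against a reference signal set
#' over an evaluation universe of triples and derives sensitivity,
#' specificity, Youden's index, PPV and NPV. In the head-to-head protocol
#' the reference is the PRR signal set — a methodological comparator taken
#' as if it were truth, not biological truth.
#'
#' @param predicted,reference character vectors of triple ids (see
#'   [triple_id()]); must be subsets of `universe`.
#' @param universe character vector of all evaluated triple ids.
#' @return list of class `confusion_metrics` with integer cells `tp`, `fp`,
#'   `fn`, `tn` and the five ratio metrics. An empty reference leaves
#'   sensitivity (and Youden) `NaN` with a warning; an empty predicted set
#'   leaves PPV `NaN` likewise.
#' @export
confusion_metrics <- function(predicted, reference, universe) {
  universe <- unique(as.character(universe))
  predicted <- unique(as.character(predicted))
  reference <- unique(as.character(reference))
  if (!all(predicted %in% universe)) stop("predicted set not a subset of universe")
  if (!all(reference %in% universe)) stop("reference set not a subset of universe")
  tp <- length(intersect(predicted, reference))
  fp <- length(setdiff(predicted, reference))
  fn <- length(setdiff(reference, predicted))
  tn <- length(universe) - tp - fp - fn
  if (tp + fn == 0L) warning("empty reference: sensitivity undefined (NaN)")
  if (tp + fp == 0L) warning("empty predicted set: PPV undefined (NaN)")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = sens, specificity = spec,
                 youden = sens + spec - 1,
                 ppv = tp / (tp + fp), npv = tn / (tn + fn)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics> tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity %.4f | specificity %.4f | Youden %.4f | PPV %.4f | NPV %.4f\n",
              x$sensitivity, x$specificity, x$youden, x$ppv, x$npv))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over every distinct score value (tied
#' scores share one threshold step), producing the (FPR, TPR) polyline from
#' (0,0) to (1,1), and integrates the AUC by the trapezoidal rule — which
#' makes the AUC identical to the Mann-Whitney pairwise-concordance
#' estimate with ties counted 1/2.
#'
#' @param scores named numeric vector: ranking score per triple id. Triples
#'   with `NA` score are excluded from the universe with a warning (they
#'   cannot be ranked).
#' @param reference character vector of positive triple ids.
#' @param universe character vector of all candidate triple ids; every
#'   element must be named in `scores`.
#' @param score_name label stored with the result.
#' @return list of class `roc_result`: `points` (data.frame `fpr`, `tpr`),
#'   `auc`, `score_name`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, reference, universe, score_name = "score") {
  universe <- unique(as.character(universe))
  reference <- unique(as.character(reference))
  if (!all(reference %in% universe)) stop("reference not a subset of universe")
  if (!all(universe %in% names(scores))) {
    stop("every universe triple needs a score or an explicit exclusion")
  }
  s <- scores[universe]
  if (anyNA(s)) {
    warning(sum(is.na(s)), " triple(s) with NA score excluded from ROC universe")
    universe <- universe[!is.na(s)]
    s <- s[universe]
  }
  lab <- universe %in% reference
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) {
    stop("degenerate ROC: reference empty or equal to universe")
  }
  o <- order(s, decreasing = TRUE)
  s <- s[o]; lab <- lab[o]
  grp <- cumsum(!duplicated(s))           # one step per distinct score
  tp_c <- cumsum(lab); fp_c <- cumsum(!lab)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp_c[last] / n_pos)
  fpr <- c(0, fp_c[last] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc, score_name = score_name,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> score=%s | AUC = %.4f | %d positives / %d negatives | %d points\n",
              x$score_name, x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Ordinary least-squares line fit
#'
#' Simple regression `y ~ x` reporting slope, intercept and the coefficient
#' of determination `R^2 = 1 - RSS/TSS`. Used for the correlation of
#' `log10(lift)` with the PRR signal intensity.
#'
#' @param x,y numeric vectors of equal length (>= 3); `x` must not be
#'   constant.
#' @return list of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
fit_line <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("degenerate fit: fewer than 3 finite points")
  if (max(x) - min(x) == 0) stop("degenerate fit: x is constant")
  fit <- lm(y ~ x)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = if (tss > 0) 1 - rss / tss else NaN,
                 n_points = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> y = %.4f x + %.4f | R^2 = %.4f | n = %d\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Head-to-head evaluation of the AR detector against the PRR detector
#'
#' Runs, per stratum, the full comparison protocol on a combined rules
#' table (as produced by [screen_triples()]): confusion metrics of the AR
#' signal flags against the PRR flags, the ROC of the lift score against
#' PRR-signal status, and the OLS fit of `log10(lift)` on the PRR signal
#' intensity `log10(PRR) + log10(chi2)` over triples where all three
#' statistics are positive and finite.
#'
#' The ROC ranking score is the lift value with the rule-count gate applied
#' first: triples below `count_gate` can never be AR signals, so the sweep
#' ranks only gated candidates (`conviction` ranking available via
#' `roc_score`).
#'
#' @param rules data.frame with columns `drug`, `stratum`, `event`,
#'   `rule_count`, `lift`, `conviction`, `prr`, `chi2`, `intensity`,
#'   `ar_signal`, `prr_signal`.
#' @param roc_score `"lift"` (default) or `"conviction"`.
#' @param count_gate rule-count gate applied to the ROC universe.
#' @return named list (one element per stratum) of lists with `confusion`,
#'   `roc`, `fit`, and `n_universe`.
#' @export
evaluate_detectors <- function(rules, roc_score = c("lift", "conviction"),
                               count_gate = 3L) {
  roc_score <- match.arg(roc_score)
  stopifnot(all(c("stratum", "rule_count", "lift", "conviction",
                  "prr", "chi2", "intensity", "ar_signal", "prr_signal")
                %in% names(rules)))
  out <- lapply(split(rules, rules$stratum), function(rb) {
    ids <- triple_id(rb)
    predicted <- ids[rb$ar_signal]
    reference <- ids[rb$prr_signal]
    conf <- confusion_metrics(predicted, reference, ids)
    gated <- rb$rule_count >= count_gate
    roc <- if (sum(gated & rb$prr_signal) > 0L &&
               sum(gated & !rb$prr_signal) > 0L) {
      sc <- setNames(rb[[roc_score]][gated], ids[gated])
      roc_curve(sc, ids[gated & rb$prr_signal], ids[gated], roc_score)
    } else NULL
    ok <- is.finite(log10(pmax(rb$lift, 0))) & is.finite(rb$intensity)
    fit <- if (sum(ok) >= 3L) fit_line(rb$intensity[ok], log10(rb$lift[ok])) else NULL
    list(confusion = conf, roc = roc, fit = fit, n_universe = length(ids))
  })
  out
}
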