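#' Stratified proportional reporting ratio
#'
#' The PRR of drug A for event C within primary-disease stratum B:
#' `(n_AB1/n_AB_plus) / (n_B1/n_B_plus)`, using only stratum-B reports.
#' It compares the reporting proportion of C among A-exposed stratum
#' reports to the proportion among the remaining stratum reports, like a
#' risk ratio on the stratum 2x2 table.
#'
#' When the comparator never reports C (`n_B1 = 0`) the statistic is
#' undefined; such rows return `NA` with a warning rather than a silent
#' `Inf`, and are excluded from downstream ROC/regression.
#'
#' @param counts a `triple_counts` data.frame; vectorized over rows.
#' @return numeric vector of non-negative PRR values (`NA` where undefined).
#' @export
prr <- function(counts) {
  if (any(counts$n_AB_plus < 1L)) {
    stop("PRR undefined: empty exposure margin (n_AB_plus = 0)")
  }
  out <- (counts$n_AB1 / counts$n_AB_plus) / (counts$n_B1 / counts$n_B_plus)
  undef <- counts$n_B1 == 0L | counts$n_B_plus == 0L
  if (any(undef)) {
    out[undef] <- NA_real_
    warning(sum(undef), " triple(s) with n_B1 = 0: PRR undefined, set to NA")
  }
  out
}

#' Yates-corrected chi-squared on the stratum 2x2 table
#'
#' Continuity-corrected chi-squared statistic for the table
#' `[[n_AB1, n_AB2], [n_B1, n_B2]]`:
#' `N * (|n_AB1*n_B2 - n_AB2*n_B1| - N/2)^2 / (n_AB_plus*n_B_plus*(n_AB1+n_B1)*(n_AB2+n_B2))`
#' with `N = n_AB_plus + n_B_plus`. When the correction `N/2` exceeds the
#' absolute cross-product difference the statistic is clamped to 0 (the
#' standard convention; squaring the negative remainder would otherwise
#' manufacture a positive statistic from a near-proportional table).
#' Tables with a zero row or column margin return `NA` with a warning.
#'
#' @inheritParams prr
#' @return numeric vector of non-negative statistics (`NA` where undefined).
#' @export
chi2_yates <- function(counts) {
  a <- as.numeric(counts$n_AB1); b <- as.numeric(counts$n_AB2)
  c_ <- as.numeric(counts$n_B1); d <- as.numeric(counts$n_B2)
  N <- a + b + c_ + d
  undef <- (a + b) == 0 | (c_ + d) == 0 | (a + c_) == 0 | (b + d) == 0
  diff <- pmax(abs(a * d - b * c_) - N / 2, 0)
  out <- N * diff^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  if (any(undef)) {
    out[undef] <- NA_real_
    warning(sum(undef), " table(s) with a zero margin: chi-squared undefined, set to NA")
  }
  out
}

#' PRR (MHRA) signal flag
#'
#' The conventional detection criteria: rule count >= `min_count`,
#' PRR >= `min_prr`, chi-squared >= `min_chi2` — all non-strict, so a
#' triple at exactly (3, 2.0, 4.0) is a signal. Undefined statistics
#' (`NA`) yield `FALSE` with a warning.
#'
#' @param rule_count,prr,chi2 numeric vectors (recycled together).
#' @param min_count,min_prr,min_chi2 thresholds.
#' @return logical vector.
#' @export
prr_signal <- function(rule_count, prr, chi2,
                       min_count = 3, min_prr = 2, min_chi2 = 4) {
  undef <- is.na(prr) | is.na(chi2)
  out <- !undef & rule_count >= min_count & prr >= min_prr & chi2 >= min_chi2
  if (any(undef)) {
    warning(sum(undef), " triple(s) with undefined PRR/chi2 treated as non-signals")
  }
  out
}

#' PRR signal intensity
#'
#' The composite magnitude `log10(PRR) + log10(chi2)` used as the
#' disproportionality side of the lift-vs-intensity correlation. Defined
#' only when both statistics are strictly positive; other rows return `NA`.
#' Base 10 is a convention — changing the base rescales the regression
#' slope but leaves its R^2 unchanged.
#'
#' @param prr,chi2 numeric vectors.
#' @return numeric vector (`NA` where undefined).
#' @export
signal_intensity <- function(prr, chi2) {
  out <- suppressWarnings(log10(prr) + log10(chi2))
  bad <- is.na(prr) | is.na(chi2) | prr <= 0 | chi2 <= 0
  out[bad] <- NA_real_
  out
}

# full PRR statistics block for a counts table
prr_metrics <- function(counts) {
  p <- suppressWarnings(prr(counts))
  x2 <- suppressWarnings(chi2_yates(counts))
  data.frame(prr = p, chi2 = x2,
             intensity = signal_intensity(p, x2),
             rule_count = counts$n_AB1)
}
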