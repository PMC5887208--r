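#' Construct an SRS dataset
#'
#' The canonical in-memory form of a spontaneous-report dataset: one report
#' per case, each report carrying a set of drugs, a set of primary-disease
#' (history) terms, and a set of adverse-event preferred terms. Reports with
#' no drug or no event rows are legitimate and contribute only to the
#' whole-database denominator \eqn{n_{++}}.
#'
#' @param case_ids character vector of unique case identifiers, in report
#'   order.
#' @param drugs,hists,events data.frames with columns `case_id` and `item`;
#'   rows whose `case_id` is not in `case_ids` are rejected.
#' @param provenance character vector of free-text notes (source files,
#'   filters applied, row counts).
#' @return An object of class `srs_dataset`.
#' @export
srs_dataset <- function(case_ids, drugs = NULL, hists = NULL, events = NULL,
                        provenance = character()) {
  case_ids <- as.character(case_ids)
  if (anyDuplicated(case_ids)) {
    stop("duplicate case_id in dataset: ",
         paste(head(unique(case_ids[duplicated(case_ids)]), 3L), collapse = ", "))
  }
  mk <- function(x, what) {
    if (is.null(x)) x <- data.table(case_id = character(), item = character())
    x <- as.data.table(x)[, .(case_id = as.character(case_id),
                              item = trimws(as.character(item)))]
    x <- unique(x[item != ""])
    bad <- setdiff(x$case_id, case_ids)
    if (length(bad)) {
      stop(what, " rows reference unknown case_id: ",
           paste(head(bad, 3L), collapse = ", "))
    }
    setkey(x, case_id, item)
    x
  }
  structure(
    list(case_ids = case_ids,
         drugs = mk(drugs, "drug"),
         hists = mk(hists, "hist"),
         events = mk(events, "event"),
         provenance = as.character(provenance)),
    class = "srs_dataset"
  )
}

#' @export
print.srs_dataset <- function(x, ...) {
  cat(sprintf("<srs_dataset> %d reports | %d drug rows | %d hist rows | %d event rows\n",
              length(x$case_ids), nrow(x$drugs), nrow(x$hists), nrow(x$events)))
  if (length(x$provenance)) cat(paste0("  ", x$provenance, "\n"), sep = "")
  invisible(x)
}

#' Number of reports in an SRS dataset
#' @param x an `srs_dataset`.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "srs_dataset"))
  length(x$case_ids)
}

#' Long-format view of an SRS dataset
#'
#' Serializes the dataset to the canonical long format with one row per
#' (case, item) pair and `item_kind` in `drug`, `hist`, `event`. Cases with
#' no items still appear once with `item_kind = "case"` and an empty item so
#' the report universe survives a round trip.
#'
#' @param x an `srs_dataset`.
#' @return a data.frame with columns `case_id`, `item_kind`, `item`.
#' @export
srs_long <- function(x) {
  stopifnot(inherits(x, "srs_dataset"))
  long <- rbind(
    data.table(case_id = x$case_ids, item_kind = "case", item = ""),
    x$drugs[, .(case_id, item_kind = "drug", item)],
    x$hists[, .(case_id, item_kind = "hist", item)],
    x$events[, .(case_id, item_kind = "event", item)]
  )
  setorder(long, case_id, item_kind, item)
  setDF(long)
  long
}

#' Reports as a list of item sets
#'
#' Convenience accessor mainly for inspection and small examples: each
#' element is a list with `drugs`, `hists`, `events` character vectors.
#'
#' @param x an `srs_dataset`.
#' @export
srs_reports <- function(x) {
  stopifnot(inherits(x, "srs_dataset"))
  split_items <- function(dt) {
    s <- split(dt$item, dt$case_id)
    s[setdiff(x$case_ids, names(s))] <- list(character())
    s[x$case_ids]
  }
  d <- split_items(x$drugs); h <- split_items(x$hists); e <- split_items(x$events)
  setNames(lapply(seq_along(x$case_ids), function(i) {
    list(drugs = d[[i]], hists = h[[i]], events = e[[i]])
  }), x$case_ids)
}
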