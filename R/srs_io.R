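#' Reader configuration for JADER-style four-table data
#'
#' Column names and row filters applied while loading DEMO/DRUG/REAC/HIST
#' tables. The defaults match the fixtures shipped with the package and the
#' output of [export_jader_tables()]; real extracts usually need at least
#' `case_id_col` and the route/role vocabulary adjusted.
#'
#' @param case_id_col name of the case-identifier column shared by all four
#'   tables.
#' @param drug_col,event_col,hist_col item columns in DRUG, REAC, HIST.
#' @param route_col,role_col optional columns in DRUG holding administration
#'   route and drug involvement (suspect/concomitant).
#' @param route_allow character allow-list for `route_col`; DRUG rows whose
#'   route is not listed are dropped (the case itself is kept). `NULL`
#'   disables route filtering. Default keeps oral medications only.
#' @param role_allow character allow-list for `role_col`; `NULL` (default)
#'   keeps every role, i.e. suspect and concomitant drugs alike.
#' @param encoding passed to the reader (`"UTF-8"` or `"Latin-1"`).
#' @return a list of class `srs_config`.
#' @export
srs_config <- function(case_id_col = "case_id",
                       drug_col = "drug", event_col = "event", hist_col = "hist",
                       route_col = "route", role_col = "role",
                       route_allow = "oral", role_allow = NULL,
                       encoding = "UTF-8") {
  structure(list(case_id_col = case_id_col, drug_col = drug_col,
                 event_col = event_col, hist_col = hist_col,
                 route_col = route_col, role_col = role_col,
                 route_allow = route_allow, role_allow = role_allow,
                 encoding = encoding),
            class = "srs_config")
}

# read one delimited table, rejecting duplicate headers up front
read_srs_table <- function(path, table_name, encoding = "UTF-8") {
  if (!file.exists(path)) {
    stop("I/O error: ", table_name, " table not found at '", path, "'")
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  hdr <- trimws(strsplit(first, sep, fixed = TRUE)[[1]])
  if (anyDuplicated(hdr)) {
    stop("schema error in ", table_name, " table: duplicate column header '",
         hdr[duplicated(hdr)][1L], "'")
  }
  fread(path, sep = sep, header = TRUE, colClasses = "character",
        encoding = encoding, data.table = TRUE)
}

require_col <- function(dt, col, table_name) {
  if (!col %in% names(dt)) {
    stop("schema error: ", table_name, " table lacks column '", col, "'")
  }
}

#' Load a JADER-style four-table dataset
#'
#' Reads the DEMO, DRUG, REAC and HIST tables, deduplicates cases,
#' applies the route/role filters to DRUG rows, and assembles the canonical
#' report set. The case universe is the deduplicated DEMO table; reports
#' lacking rows in DRUG/REAC/HIST get empty corresponding sets. All terms
#' are whitespace-trimmed; matching downstream is exact string equality.
#'
#' @param demo_path,drug_path,reac_path,hist_path paths to the four
#'   delimited text tables (comma- or tab-separated, header row required).
#' @param config an [srs_config()].
#' @return an [srs_dataset()] whose provenance records row counts before and
#'   after every filter.
#' @export
load_dataset <- function(demo_path, drug_path, reac_path, hist_path,
                         config = srs_config()) {
  stopifnot(inherits(config, "srs_config"))
  id <- config$case_id_col
  prov <- character()
  note <- function(fmt, ...) prov <<- c(prov, sprintf(fmt, ...))

  demo <- read_srs_table(demo_path, "DEMO", config$encoding)
  drug <- read_srs_table(drug_path, "DRUG", config$encoding)
  reac <- read_srs_table(reac_path, "REAC", config$encoding)
  hist <- read_srs_table(hist_path, "HIST", config$encoding)
  for (t in list(list(demo, "DEMO"), list(drug, "DRUG"),
                 list(reac, "REAC"), list(hist, "HIST"))) {
    require_col(t[[1]], id, t[[2]])
  }
  require_col(drug, config$drug_col, "DRUG")
  require_col(reac, config$event_col, "REAC")
  require_col(hist, config$hist_col, "HIST")

  # deduplicate cases: first occurrence wins, file order preserved
  n0 <- nrow(demo)
  case_ids <- trimws(demo[[id]])
  case_ids <- case_ids[!duplicated(case_ids)]
  note("DEMO: %d rows, %d unique cases retained", n0, length(case_ids))

  n0 <- nrow(drug)
  drug[, (id) := trimws(get(id))]
  drug <- drug[get(id) %chin% case_ids]
  if (!is.null(config$route_allow) && config$route_col %in% names(drug)) {
    drug <- drug[trimws(get(config$route_col)) %chin% config$route_allow]
    note("DRUG: %d rows, %d after case/route filter (allow: %s)",
         n0, nrow(drug), paste(config$route_allow, collapse = ","))
  } else {
    note("DRUG: %d rows, %d after case filter (no route filter)", n0, nrow(drug))
  }
  if (!is.null(config$role_allow) && config$role_col %in% names(drug)) {
    n1 <- nrow(drug)
    drug <- drug[trimws(get(config$role_col)) %chin% config$role_allow]
    note("DRUG: %d rows, %d after role filter (allow: %s)",
         n1, nrow(drug), paste(config$role_allow, collapse = ","))
  }

  keep_case <- function(dt, nm) {
    n0 <- nrow(dt)
    dt[, (id) := trimws(get(id))]
    dt <- dt[get(id) %chin% case_ids]
    note("%s: %d rows, %d after case filter", nm, n0, nrow(dt))
    dt
  }
  reac <- keep_case(reac, "REAC")
  hist <- keep_case(hist, "HIST")

  pairs <- function(dt, col) data.table(case_id = dt[[id]], item = dt[[col]])
  srs_dataset(case_ids,
              drugs = pairs(drug, config$drug_col),
              hists = pairs(hist, config$hist_col),
              events = pairs(reac, config$event_col),
              provenance = prov)
}

#' Define a primary-disease stratum
#'
#' A stratum is a named primary disease given as a non-empty set of
#' preferred terms (standing in for a licensed MedDRA SMQ term list).
#'
#' @param name stratum label, unique across strata.
#' @param terms character vector of history preferred terms.
#' @export
stratum_definition <- function(name, terms) {
  terms <- unique(trimws(as.character(terms)))
  terms <- terms[terms != ""]
  if (!length(terms)) stop("validation error: stratum '", name, "' has an empty term set")
  structure(list(name = as.character(name), terms = terms),
            class = "stratum_definition")
}

# normalize strata input: list of stratum_definition, or named list of term vectors
as_strata <- function(strata) {
  if (inherits(strata, "stratum_definition")) strata <- list(strata)
  out <- lapply(seq_along(strata), function(i) {
    s <- strata[[i]]
    if (inherits(s, "stratum_definition")) s
    else stratum_definition(names(strata)[i], s)
  })
  nms <- vapply(out, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("validation error: duplicate stratum names")
  setNames(out, nms)
}

#' Read stratum definitions from disk
#'
#' Accepts either a YAML file mapping stratum name to a list of preferred
#' terms, or a named character vector of paths to one-term-per-line text
#' files (names become stratum names).
#'
#' @param path YAML file path, or named character vector of term-list files.
#' @return named list of [stratum_definition()] objects.
#' @export
read_strata <- function(path) {
  if (length(path) == 1L && is.null(names(path))) {
    m <- yaml::read_yaml(path)
    if (!is.list(m) || is.null(names(m))) {
      stop("schema error: strata YAML must map stratum name -> term list")
    }
    as_strata(lapply(m, unlist))
  } else {
    if (is.null(names(path)) || any(names(path) == "")) {
      stop("term-list files must be a named character vector (name = stratum)")
    }
    as_strata(lapply(path, function(p) readLines(p, warn = FALSE)))
  }
}

#' Assign reports to primary-disease strata
#'
#' A case belongs to a stratum iff its history terms intersect the stratum's
#' term set; a case may belong to several strata (and to none).
#'
#' @param dataset an [srs_dataset()].
#' @param strata strata as accepted by [stratum_definition()]: a named list
#'   of term vectors or of `stratum_definition` objects.
#' @return named list mapping stratum name to a character vector of case ids
#'   (in report order).
#' @export
annotate_strata <- function(dataset, strata) {
  stopifnot(inherits(dataset, "srs_dataset"))
  strata <- as_strata(strata)
  lapply(strata, function(s) {
    ids <- unique(dataset$hists[item %chin% s$terms, case_id])
    dataset$case_ids[dataset$case_ids %chin% ids]
  })
}
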