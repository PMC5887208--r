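write_tables <- function(dir, demo, drug, reac, hist) {
  paths <- file.path(dir, c("demo.csv", "drug.csv", "reac.csv", "hist.csv"))
  writeLines(demo, paths[1]); writeLines(drug, paths[2])
  writeLines(reac, paths[3]); writeLines(hist, paths[4])
  as.list(setNames(paths, c("demo", "drug", "reac", "hist")))
}

test_that("single-case identity load and per-table filters", {
  d <- withr::local_tempdir()
  p <- write_tables(d,
    demo = c("case_id,sex,age", "C1,female,60"),
    drug = c("case_id,drug,role,route", "C1,D1,suspect,oral"),
    reac = c("case_id,event", "C1,E1"),
    hist = c("case_id,hist", "C1,H1"))
  ds <- load_dataset(p$demo, p$drug, p$reac, p$hist)
  expect_equal(ds$case_ids, "C1")
  expect_equal(ds$drugs$item, "D1")
  expect_equal(ds$hists$item, "H1")
  expect_equal(ds$events$item, "E1")

  # non-oral drug rows are dropped; the case itself survives
  p2 <- write_tables(d,
    demo = c("case_id", "C2"),
    drug = c("case_id,drug,role,route", "C2,D9,suspect,injection"),
    reac = c("case_id,event", "C2,E1"),
    hist = c("case_id,hist", "C2,H1"))
  ds2 <- load_dataset(p2$demo, p2$drug, p2$reac, p2$hist)
  expect_equal(ds2$case_ids, "C2")
  expect_equal(nrow(ds2$drugs), 0L)
  # disabling the route filter keeps the row
  ds3 <- load_dataset(p2$demo, p2$drug, p2$reac, p2$hist,
                      srs_config(route_allow = NULL))
  expect_equal(ds3$drugs$item, "D9")
  # role filter is off by default, on when configured
  ds4 <- load_dataset(p$demo, p$drug, p$reac, p$hist,
                      srs_config(role_allow = "concomitant"))
  expect_equal(nrow(ds4$drugs), 0L)
})

test_that("duplicate cases are deduplicated, first occurrence wins, idempotently", {
  d <- withr::local_tempdir()
  p <- write_tables(d,
    demo = c("case_id,sex", "C1,female", "C2,male", "C1,male"),
    drug = c("case_id,drug,route", "C1,D1,oral", "C1,D1,oral", "C2,D2,oral"),
    reac = c("case_id,event", "C1,E1", "C2,E2", "C2,E2"),
    hist = c("case_id,hist", "C1,H1"))
  ds <- load_dataset(p$demo, p$drug, p$reac, p$hist)
  expect_equal(ds$case_ids, c("C1", "C2"))
  # a report listing an item twice carries it once
  expect_equal(nrow(ds$drugs[ds$drugs$case_id == "C1", ]), 1L)
  expect_equal(nrow(ds$events[ds$events$case_id == "C2", ]), 1L)
  # loading twice yields identical report sets
  ds_again <- load_dataset(p$demo, p$drug, p$reac, p$hist)
  expect_identical(srs_long(ds), srs_long(ds_again))
})

test_that("I/O and schema errors name the offending table", {
  d <- withr::local_tempdir()
  p <- write_tables(d,
    demo = c("case_id", "C1"),
    drug = c("case_id,drug", "C1,D1"),
    reac = c("case_id,event", "C1,E1"),
    hist = c("case_id,hist", "C1,H1"))
  expect_error(load_dataset(file.path(d, "nope.csv"), p$drug, p$reac, p$hist),
               "DEMO.*not found")
  writeLines(c("ident,drug", "C1,D1"), p$drug)
  expect_error(load_dataset(p$demo, p$drug, p$reac, p$hist),
               "schema error: DRUG.*case_id")
  writeLines(c("case_id,drug,drug", "C1,D1,D2"), p$drug)
  expect_error(load_dataset(p$demo, p$drug, p$reac, p$hist),
               "duplicate column header")
})

test_that("stratum membership is set intersection; multi-stratum cases allowed", {
  ds <- reports_to_dataset(list(
    list(drugs = "D1", hists = "H1", events = "E1"),
    list(drugs = "D1", hists = "H3", events = "E1"),
    list(drugs = character(), hists = c("H1", "H9"), events = character())
  ), ids = c("A", "B", "C"))
  m <- annotate_strata(ds, list(K = c("H1", "H2"), L = "H9"))
  expect_equal(m$K, c("A", "C"))
  expect_equal(m$L, "C")
  expect_error(annotate_strata(ds, list(K = character())), "empty term set")
  expect_error(annotate_strata(ds, list(K = "H1", K = "H2")), "duplicate stratum")
})

test_that("membership equals brute-force intersection on random reports", {
  set.seed(42)
  for (rep in 1:5) {
    reports <- random_reports(80)
    ds <- reports_to_dataset(reports)
    strata <- list(S1 = c("H1", "H2"), S2 = "H3")
    m <- annotate_strata(ds, strata)
    for (b in names(strata)) {
      manual <- ds$case_ids[vapply(reports, function(r) {
        length(intersect(r$hists, strata[[b]])) > 0
      }, logical(1))]
      expect_equal(m[[b]], manual)
    }
  }
})

test_that("strata round-trip through YAML and term-list files", {
  d <- withr::local_tempdir()
  yml <- file.path(d, "strata.yaml")
  yaml::write_yaml(list(kidney = list("H1", "H2"), liver = list("H3")), yml)
  st <- read_strata(yml)
  expect_equal(st$kidney$terms, c("H1", "H2"))
  txt <- file.path(d, "kidney.txt")
  writeLines(c("H1", "H2"), txt)
  st2 <- read_strata(c(kidney = txt))
  expect_equal(st2$kidney$terms, c("H1", "H2"))
})
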