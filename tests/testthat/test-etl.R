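write_table <- function(path, header, rows) {
  writeLines(c(header, rows), path)
}

test_that("the parser returns one record per data row and keeps extra columns", {
  d <- withr::local_tempdir()
  write_table(file.path(d, "DEMO.txt"),
              "primaryid$caseid$fda_dt$event_dt$sex$age$age_cod$wt$wt_cod$occr_country$extra",
              c("1$100$20230101$20221201$F$62$YR$70$KG$US$x",
                "2$101$20230102$20221215$M$54$YR$$$$y",
                "3$102$20230103$$$$$$$JP$z"))
  tbl <- read_faers_tables(c(demo = file.path(d, "DEMO.txt")))
  expect_equal(nrow(tbl$demo), 3)
  expect_true("extra" %in% names(tbl$demo))
})

test_that("a missing mandatory column is a schema error naming table and column", {
  d <- withr::local_tempdir()
  write_table(file.path(d, "DRUG.txt"),
              "primaryid$drug_seq$drugname",
              "1$1$TAXOL")
  expect_error(read_faers_tables(c(drug = file.path(d, "DRUG.txt"))),
               "DRUG\\.role_cod", class = "faersignal_schema_error")
})

test_that("generator output round-trips through the parser with equal row counts", {
  sim <- simulate_faers(sim_config(n_reports = 500, seed = 2))
  d <- withr::local_tempdir()
  write_faers_tables(sim, d)
  raw <- read_faers_tables(d)
  for (nm in c("demo", "drug", "reac", "ther", "indi")) {
    expect_equal(nrow(raw[[nm]]), nrow(sim$tables[[nm]]), label = nm)
  }
})

test_that("deduplication keeps the latest version, breaking ties by primaryid", {
  demo <- tibble::tibble(
    primaryid = c("1001", "1002", "2001", "3001", "3002"),
    caseid = c("100", "100", "200", "300", "300"),
    fda_dt = c("20230101", "20230601", "20230301", "20230401", "20230401")
  )
  kept <- deduplicate_cases(demo)
  expect_setequal(kept$primaryid, c("1002", "2001", "3002"))
  expect_equal(attr(kept, "n_removed"), 2L)
  # idempotence
  again <- deduplicate_cases(kept)
  expect_equal(again$primaryid, kept$primaryid)
  expect_equal(attr(again, "n_removed"), 0L)
})

test_that("deduplication is the identity when no caseid repeats", {
  demo <- tibble::tibble(primaryid = as.character(1:4),
                         caseid = as.character(11:14),
                         fda_dt = rep("20230101", 4))
  expect_equal(deduplicate_cases(demo)$primaryid, demo$primaryid)
  empty <- demo[0, ]
  expect_equal(nrow(deduplicate_cases(empty)), 0)
})

test_that("drug names are case-folded, squished and mapped through synonyms", {
  out <- normalize_drug_name(c("TAXOL", "  Irinotecan   HCl ", "drugzz"),
                             toy_synonyms())
  expect_equal(as.character(out), c("paclitaxel", "irinotecan", "drugzz"))
  expect_equal(attr(out, "n_unmapped"), 1L)
  # data-frame form of the map works too
  map_df <- tibble::tibble(raw = "oncovin", standard = "vincristine")
  expect_equal(as.character(normalize_drug_name("Oncovin", map_df)),
               "vincristine")
})

test_that("ages are converted to years with range and unit guards", {
  expect_equal(harmonize_age(24, "MON"), 2)
  expect_equal(harmonize_age(6.2, "DEC"), 62)
  expect_equal(harmonize_age(730.5, "DY"), 2)
  expect_warning(res <- harmonize_age(200, "YR"), "outside")
  expect_true(is.na(res))
  expect_warning(res2 <- harmonize_age(5, "FORTNIGHT"), "unknown unit")
  expect_true(is.na(res2))
  # pure and order-independent
  v <- c(24, 6.2, 50)
  u <- c("MON", "DEC", "YR")
  expect_equal(harmonize_age(v, u)[c(3, 1, 2)],
               harmonize_age(v[c(3, 1, 2)], u[c(3, 1, 2)]))
})

test_that("weights are converted to kilograms with range guards", {
  expect_equal(harmonize_weight(154.3, "LBS"), 69.99, tolerance = 1e-3)
  expect_equal(harmonize_weight(70, "KG"), 70)
  expect_equal(harmonize_weight(70000, "GMS"), 70)
  expect_true(is.na(harmonize_weight(0, "KG")))
  expect_true(is.na(harmonize_weight(600, "KG")))
})

test_that("reactions gain their primary SOC, unknown PTs are UNMAPPED", {
  out <- attach_meddra(c("Neutropenia", "Totally novel PT"), toy_dict())
  expect_equal(out$soc, c("Blood and lymphatic system disorders", "UNMAPPED"))
  expect_equal(attr(out, "n_unmapped"), 1L)
  empty <- attach_meddra(character(0), toy_dict())
  expect_equal(nrow(empty), 0)
})

test_that("case assembly joins tables, applies dedup first, drops orphans", {
  raw <- list(
    demo = tibble::tibble(
      primaryid = c("1", "2", "9"),
      caseid = c("100", "100", "300"),
      fda_dt = c("20230101", "20230601", "20230601"),
      event_dt = c("20221201", "20221201", "2022"),
      sex = c("F", "F", ""), age = c("62", "62", ""),
      age_cod = c("YR", "YR", ""), wt = c("70", "70", ""),
      wt_cod = c("KG", "KG", ""), occr_country = c("US", "US", "")
    ),
    drug = tibble::tibble(
      primaryid = c("2", "2", "9"), drug_seq = c("1", "2", "1"),
      role_cod = c("PS", "SS", "PS"),
      drugname = c("TAXOL", "ONCOVIN", "IRINOTECAN HCL")
    ),
    reac = tibble::tibble(
      primaryid = c("2", "2", "2", "999"),
      pt = c("Nausea", "Neutropenia", "Dyspnoea", "Nausea")
    ),
    ther = tibble::tibble(primaryid = "2", dsg_drug_seq = "1",
                          start_dt = "20221101"),
    indi = tibble::tibble(primaryid = "2", indi_drug_seq = "1",
                          indi_pt = "Breast cancer")
  )
  expect_warning(
    cases <- build_case_reports(raw, toy_synonyms(), toy_dict()),
    "unknown primaryid"
  )
  expect_equal(nrow(cases$demo), 2)           # dedup kept one of caseid 100
  expect_true("2" %in% cases$demo$primaryid)  # the later version
  r2 <- cases$drugs[cases$drugs$primaryid == "2", ]
  expect_equal(nrow(r2), 2)
  expect_setequal(r2$standard_name, c("paclitaxel", "vincristine"))
  expect_equal(r2$start_precision[r2$drug_seq == "1"], "day")
  expect_equal(nrow(cases$reactions[cases$reactions$primaryid == "2", ]), 3)
  # partial event date flagged, not dated
  expect_equal(cases$demo$event_precision[cases$demo$primaryid == "9"], "year")
  expect_true(is.na(cases$demo$event_date[cases$demo$primaryid == "9"]))
})

test_that("with injected duplicates the case count equals unique caseids", {
  cfg <- sim_config(n_reports = 800, duplicate_fraction = 0.1, seed = 21)
  sim <- simulate_faers(cfg)
  cases <- build_case_reports(sim$tables)
  expect_equal(nrow(cases$demo), 800)
  expect_equal(nrow(cases$demo), length(unique(sim$tables$demo$caseid)))
  # conservation: never more cases than DEMO rows
  expect_lte(nrow(cases$demo), nrow(sim$tables$demo))
})

test_that("empty REAC yields reports with empty reaction sets", {
  raw <- list(
    demo = tibble::tibble(primaryid = "1", caseid = "1", fda_dt = "20230101",
                          event_dt = "", sex = "F", age = "", age_cod = "",
                          wt = "", wt_cod = "", occr_country = ""),
    drug = tibble::tibble(primaryid = "1", drug_seq = "1", role_cod = "PS",
                          drugname = "TAXOL"),
    reac = tibble::tibble(primaryid = character(), pt = character()),
    ther = NULL, indi = NULL
  )
  cases <- build_case_reports(raw)
  expect_equal(nrow(cases$demo), 1)
  expect_equal(nrow(cases$reactions), 0)
})
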