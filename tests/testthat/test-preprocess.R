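# Screening: deduplication, drug matching, window and missing-info
# exclusion, SOC annotation.

test_that("deduplication keeps the highest case version with deterministic tie-breaks", {
  cases <- make_cases(list(
    list(id = "A1", caseid = "A", version = 1, fda = "2021-01-01"),
    list(id = "A2", caseid = "A", version = 2, fda = "2021-02-01"),
    list(id = "A3", caseid = "A", version = 3, fda = "2021-03-01"),
    # tie on version: later fda_dt wins
    list(id = "B1", caseid = "B", version = 1, fda = "2021-01-01"),
    list(id = "B2", caseid = "B", version = 1, fda = "2021-06-01"),
    # tie on version and date: larger primaryid wins
    list(id = "C1", caseid = "C", version = 2, fda = "2021-01-01"),
    list(id = "C9", caseid = "C", version = 2, fda = "2021-01-01"),
    # unique case untouched
    list(id = "D1", caseid = "D", version = 1, fda = "2021-01-01")
  ))
  dd <- deduplicate(cases)
  expect_setequal(dd$demo$primaryid, c("A3", "B2", "C9", "D1"))
  # idempotent
  dd2 <- deduplicate(dd)
  expect_equal(dd2$demo, dd$demo)
  # member tables follow the demo table
  expect_true(all(dd$reactions$primaryid %in% dd$demo$primaryid))
})

test_that("deduplication recovers the generator's unique-case count", {
  cfg <- sim_config(n_target_reports = 300, n_background_reports = 300,
                    duplicate_rate = 0.2, seed = 5)
  gen <- generate_reports(cfg)
  cases <- suppressWarnings(assemble_cases(gen$raw))
  expect_equal(n_cases(cases),
               gen$truth$n_unique_cases + gen$truth$n_duplicate_rows)
  dd <- deduplicate(cases)
  expect_equal(n_cases(dd), gen$truth$n_unique_cases)
  # the kept record for duplicated cases is the superseding version
  dup_ids <- gen$truth$case_truth$caseid[gen$truth$case_truth$n_versions == 2]
  kept <- dd$demo[dd$demo$caseid %in% dup_ids, ]
  expect_true(all(kept$caseversion == 2L))
})

test_that("drug matching is substring-based, case-insensitive, and respects the PS restriction", {
  cfg <- screening_config()
  cases <- make_cases(list(
    list(id = "1", drugs = list(c("TABRECTA 400MG", "PS"))),
    list(id = "2", drugs = list(c("capmatinib", "C"))),
    list(id = "3", drugs = list(c("DRUG_007", "PS"))),
    list(id = "4", drugs = list(c("Tabrecta tablet", "SS"), c("DRUG_001", "PS")))
  ))
  expect_equal(match_target_drug(cases, cfg), c(TRUE, FALSE, FALSE, FALSE))
  cfg_any <- screening_config(require_primary_suspect = FALSE)
  expect_equal(match_target_drug(cases, cfg_any), c(TRUE, TRUE, FALSE, TRUE))
})

test_that("screening matches the generator's planted exposure set", {
  cfg <- sim_config(n_target_reports = 400, n_background_reports = 400,
                    duplicate_rate = 0.15, seed = 9)
  gen <- generate_reports(cfg)
  cases <- suppressWarnings(assemble_cases(gen$raw))
  scr <- screen(cases)
  truth <- gen$truth$case_truth
  expect_setequal(scr$target$demo$caseid, truth$caseid[truth$exposed])
  expect_setequal(scr$background$demo$caseid, truth$caseid[!truth$exposed])
})

test_that("screening excludes by window, keeps partially-missing reports, and conserves counts", {
  cases <- make_cases(list(
    list(id = "1", fda = "2019-05-01"),                        # before window
    list(id = "2", fda = "2024-02-01"),                        # after window
    list(id = "3", fda = "2022-06-01", sex = "F"),             # only sex known
    list(id = "4", fda = "2022-06-01"),                        # fully anonymous
    list(id = "5", fda = "2022-06-01", sex = "M", age = 60,
         country = "FRANCE", reporter = "physician",
         drugs = list(c("DRUG_001", "PS")))
  ))
  scr <- screen(cases, screening_config())
  log <- scr$log
  expect_equal(log$count[log$reason == "out_of_window"], 2L)
  expect_equal(log$count[log$reason == "all_demographics_missing"], 1L)
  expect_setequal(scr$target$demo$primaryid, "3")
  expect_setequal(scr$background$demo$primaryid, "5")
  expect_equal(sum(log$count), n_cases(cases))  # conservation

  # disabling the missing-info exclusion keeps the anonymous report
  scr2 <- screen(cases, screening_config(exclude_missing_all_demographics = FALSE))
  expect_true("4" %in% scr2$target$demo$primaryid)
})

test_that("the surviving case set is invariant under input order", {
  cfg <- sim_config(n_target_reports = 120, n_background_reports = 120,
                    duplicate_rate = 0.3, seed = 21)
  gen <- generate_reports(cfg)
  cases <- suppressWarnings(assemble_cases(gen$raw))
  shuffled <- cases
  perm <- withr::with_seed(99, sample.int(nrow(cases$demo)))
  shuffled$demo <- shuffled$demo[perm, ]
  s1 <- screen(cases)
  s2 <- screen(shuffled)
  expect_setequal(s1$target$demo$primaryid, s2$target$demo$primaryid)
  expect_setequal(s1$background$demo$primaryid, s2$background$demo$primaryid)
})

test_that("SOC annotation tags mapped PTs and counts unmapped ones", {
  dir <- withr::local_tempdir()
  writeLines(c("pt,soc_name,soc_code",
               "Oedema,General disorders and administration site conditions,10018065"),
             file.path(dir, "map.csv"))
  map <- read_meddra_map(file.path(dir, "map.csv"))
  cases <- make_cases(list(
    list(id = "1", pts = c("OEDEMA", "MYSTERY TERM"))
  ))
  ann <- suppressMessages(annotate_soc(cases, map))
  expect_equal(ann$reactions$soc_name,
               c("General disorders and administration site conditions",
                 "UNMAPPED"))
  log <- attr(ann, "log")
  expect_equal(log$count[log$reason == "unmapped_pt_occurrences"], 1L)

  # the generator's own catalog map leaves nothing unmapped
  gen <- generate_reports(sim_config(n_target_reports = 50,
                                     n_background_reports = 50, seed = 3))
  cs <- suppressWarnings(assemble_cases(gen$raw))
  ann2 <- annotate_soc(cs, truth_meddra_map(gen$truth))
  expect_equal(sum(ann2$reactions$soc_name == "UNMAPPED"), 0)
})
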