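# Four-grid construction at PT and SOC level under both counting
# policies.

# split a raw (non-deduplicated) case set on the default drug synonyms
filter_screen_target <- function(cases) {
  hit <- match_target_drug(cases, screening_config())
  out <- cases
  out$demo <- cases$demo[hit, ]
  out$reactions <- cases$reactions[cases$reactions$primaryid %in% out$demo$primaryid, ]
  out
}
filter_screen_background <- function(cases) {
  hit <- match_target_drug(cases, screening_config())
  out <- cases
  out$demo <- cases$demo[!hit, ]
  out$reactions <- cases$reactions[cases$reactions$primaryid %in% out$demo$primaryid, ]
  out
}

two_report_screened <- function() {
  target <- make_cases(list(
    list(id = "T1", pts = c("X", "Y")),
    list(id = "T2", pts = "X")
  ))
  background <- make_cases(list(
    list(id = "B1", pts = "Y", drugs = list(c("DRUG_001", "PS")))
  ))
  make_screened(target, background)
}

test_that("pair counting enumerates (report, PT) occurrences", {
  tabs <- build_pt_tables(two_report_screened())
  x <- tabs[tabs$event_id == "X", ]
  expect_equal(unlist(x[c("a", "b", "c", "d")], use.names = FALSE),
               c(2L, 1L, 0L, 1L))
  y <- tabs[tabs$event_id == "Y", ]
  expect_equal(unlist(y[c("a", "b", "c", "d")], use.names = FALSE),
               c(1L, 2L, 1L, 0L))
  expect_equal(attr(tabs, "N"), 4L)
})

test_that("a single report with a single PT and no background gives the degenerate grid", {
  scr <- make_screened(
    make_cases(list(list(id = "T1", pts = "X"))),
    make_cases(list())
  )
  scr$background$demo <- scr$target$demo[0, ]
  scr$background$reactions <- scr$target$reactions[0, ]
  tabs <- build_pt_tables(scr)
  expect_equal(unlist(tabs[1, c("a", "b", "c", "d")], use.names = FALSE),
               c(1L, 0L, 0L, 0L))
})

test_that("report counting uses distinct reports as the unit", {
  tabs <- build_pt_tables(two_report_screened(),
                          counting_policy("report"))
  x <- tabs[tabs$event_id == "X", ]
  # 2 of 2 target reports carry X; 0 of 1 background reports
  expect_equal(unlist(x[c("a", "b", "c", "d")], use.names = FALSE),
               c(2L, 0L, 0L, 1L))
  expect_equal(attr(tabs, "N"), 3L)
})

test_that("margins are shared across all tables and occurrences are conserved", {
  gen <- generate_reports(sim_config(n_target_reports = 500,
                                     n_background_reports = 500, seed = 14))
  cases <- suppressWarnings(assemble_cases(gen$raw))
  scr <- screen(cases)
  tabs <- build_pt_tables(scr)
  expect_true(all(tabs$a + tabs$b == tabs$a[1] + tabs$b[1]))
  expect_true(all(tabs$c + tabs$d == tabs$c[1] + tabs$d[1]))
  expect_equal(sum(tabs$a), nrow(scr$target$reactions))
})

test_that("SOC tables aggregate member-PT occurrences and drop unmapped ones", {
  target <- make_cases(list(
    list(id = "T1", pts = c("X1", "X2", "Z")),  # X1, X2 share a SOC
    list(id = "T2", pts = c("X1", "W"))         # W is unmapped
  ))
  background <- make_cases(list(
    list(id = "B1", pts = c("X1", "Z"), drugs = list(c("DRUG_001", "PS")))
  ))
  scr <- make_screened(target, background)
  dir <- withr::local_tempdir()
  writeLines(c("pt,soc_name,soc_code",
               "X1,SOC_A,100", "X2,SOC_A,100", "Z,SOC_B,200"),
             file.path(dir, "map.csv"))
  scr <- suppressMessages(annotate_soc(scr, read_meddra_map(file.path(dir, "map.csv"))))
  tabs <- build_soc_tables(scr)
  soc_a <- tabs[tabs$event_id == "SOC_A", ]
  # three (report, PT) occurrences map into SOC_A from the target arm
  expect_equal(soc_a$a, 3L)
  soc_b <- tabs[tabs$event_id == "SOC_B", ]
  expect_equal(soc_b$a, 1L)
  # the unmapped occurrence (W) is excluded from the margins
  expect_equal(soc_a$a + soc_a$b, 4L)
  expect_equal(attr(tabs, "n_unmapped"), 1L)

  # SOC a equals the sum of member-PT a values
  pt_tabs <- build_pt_tables(scr)
  expect_equal(soc_a$a, sum(pt_tabs$a[pt_tabs$event_id %in% c("X1", "X2")]))

  # building SOC tables without annotation is a stage error
  expect_error(build_soc_tables(make_screened(target, background)),
               "annotate_soc", class = "faersignal_stage_error")
})

test_that("pipeline tables equal truth tables exactly once duplicates are removed", {
  planted <- tibble::tibble(pt = "AE_TERM_010", rr = 5)
  cfg0 <- sim_config(n_target_reports = 400, n_background_reports = 400,
                     planted_signals = planted, duplicate_rate = 0, seed = 31)
  gen0 <- generate_reports(cfg0)
  tabs0 <- build_pt_tables(screen(suppressWarnings(assemble_cases(gen0$raw))))
  tt0 <- truth_tables(gen0$truth)
  expect_equal(tibble::as_tibble(tabs0), tibble::as_tibble(tt0), ignore_attr = TRUE)

  cfg1 <- sim_config(n_target_reports = 400, n_background_reports = 400,
                     planted_signals = planted, duplicate_rate = 0.3, seed = 31)
  gen1 <- generate_reports(cfg1)
  cases1 <- suppressWarnings(assemble_cases(gen1$raw))
  # without deduplication the occurrence counts are inflated
  tabs_dirty <- build_pt_tables(make_screened(
    filter_screen_target(cases1), filter_screen_background(cases1)
  ))
  tt1 <- truth_tables(gen1$truth)
  expect_gt(sum(tabs_dirty$a), sum(tt1$a))
  # the screened pipeline (which deduplicates) matches truth exactly
  tabs1 <- build_pt_tables(screen(cases1))
  expect_equal(tibble::as_tibble(tabs1), tibble::as_tibble(tt1), ignore_attr = TRUE)
})

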