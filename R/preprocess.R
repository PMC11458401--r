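# Screening of case reports: date window, deduplication by case
# version, exclusion of reports with no usable patient information, and
# the target / background split on the drug of interest.

#' Screening configuration
#'
#' Bundles the report-screening rules: the drug-name synonym list (both
#' the trade and generic name by default), whether only primary-suspect
#' (PS) drug records count as exposure, the minimum report count a
#' drug-event pair needs before it is evaluated against the signal
#' thresholds, whether to drop reports whose patient information is
#' entirely missing, and the extraction window in calendar quarters.
#'
#' `min_pair_count` is applied at signal-evaluation time as the `a >= 3`
#' gate of the ROR/PRR thresholds (see [signal_thresholds()]), not as a
#' per-report filter: a pair with fewer target reports than this is
#' never called a signal.
#'
#' A report is excluded for missing patient information only when sex,
#' age, country and reporter are all missing; any single present field
#' keeps the report (missing fields fall into "Unknown" strata of the
#' descriptive summary).
#'
#' @param drug_synonyms character vector of names identifying the target
#'   drug (substring match, case-insensitive) in `drugname` or `prod_ai`.
#' @param require_primary_suspect only role code `PS` counts as exposure
#'   (default `TRUE`).
#' @param min_pair_count minimum `a` for threshold evaluation (default 3).
#' @param exclude_missing_all_demographics drop fully anonymous reports
#'   (default `TRUE`).
#' @param date_window length-2 character vector of quarter labels,
#'   e.g. `c("2020Q2", "2023Q4")`; reports are kept when their FDA
#'   receipt date falls inside the window (missing dates are kept).
#' @return A `screening_config` list.
#' @export
screening_config <- function(drug_synonyms = c("TABRECTA", "CAPMATINIB"),
                             require_primary_suspect = TRUE,
                             min_pair_count = 3L,
                             exclude_missing_all_demographics = TRUE,
                             date_window = c("2020Q2", "2023Q4")) {
  if (length(drug_synonyms) < 1 || any(!nzchar(drug_synonyms))) {
    abort("'drug_synonyms' must be a non-empty character vector",
          class = "faersignal_config_error")
  }
  stopifnot_scalar_count(min_pair_count, "min_pair_count")
  if (length(date_window) != 2) {
    abort("'date_window' must be c(start_quarter, end_quarter)",
          class = "faersignal_config_error")
  }
  if (quarter_start(date_window[1]) > quarter_end(date_window[2])) {
    abort("empty date window: start quarter is after end quarter",
          class = "faersignal_config_error")
  }
  structure(
    list(
      drug_synonyms = norm_term(drug_synonyms),
      require_primary_suspect = isTRUE(require_primary_suspect),
      min_pair_count = as.integer(min_pair_count),
      exclude_missing_all_demographics = isTRUE(exclude_missing_all_demographics),
      date_window = date_window
    ),
    class = "screening_config"
  )
}

#' Deduplicate case reports by case version
#'
#' FAERS carries one row per report *version*; later versions supersede
#' earlier ones. For each `caseid` exactly one record is kept: the
#' highest `caseversion`, ties broken by the latest FDA receipt date,
#' then by the lexicographically largest `primaryid`. The rule is fully
#' deterministic, so deduplication is idempotent and independent of
#' input order.
#'
#' @param cases a `faers_cases` object.
#' @return The deduplicated `faers_cases`; the number of removed
#'   versions is appended to the log attribute.
#' @export
deduplicate <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  demo <- cases$demo
  if (nrow(demo) == 0) return(cases)
  fda_key <- as.numeric(demo$fda_dt)
  fda_key[is.na(fda_key)] <- -Inf
  ord <- order(demo$caseid, demo$caseversion, fda_key, demo$primaryid,
               method = "radix", decreasing = c(FALSE, TRUE, TRUE, TRUE))
  demo_sorted <- demo[ord, ]
  keep <- demo_sorted$primaryid[!duplicated(demo_sorted$caseid)]
  removed <- nrow(demo) - length(keep)
  out <- filter_cases(cases, keep)
  attr(out, "log") <- dplyr::bind_rows(
    attr(cases, "log"),
    tibble::tibble(step = "deduplicate", reason = "superseded_case_version",
                   count = as.integer(removed))
  )
  out
}

#' Which reports name the target drug?
#'
#' A report matches when any of its drug records contains one of the
#' configured synonyms as a substring (case-insensitive, on `drugname`
#' or on the active-ingredient field `prod_ai` — FAERS free-text drug
#' names often carry dose or formulation suffixes) and, if
#' `require_primary_suspect`, that record's role code is `PS`.
#'
#' @param cases a `faers_cases` object.
#' @param cfg a [screening_config()].
#' @return Logical vector aligned with `cases$demo`, `TRUE` for target
#'   reports.
#' @export
match_target_drug <- function(cases, cfg) {
  stopifnot(inherits(cases, "faers_cases"), inherits(cfg, "screening_config"))
  drugs <- cases$drugs
  if (nrow(drugs) == 0) return(rep(FALSE, nrow(cases$demo)))
  name1 <- norm_term(drugs$drugname)
  name2 <- norm_term(ifelse(is.na(drugs$prod_ai), "", drugs$prod_ai))
  hit <- rep(FALSE, nrow(drugs))
  for (syn in cfg$drug_synonyms) {
    hit <- hit | stringr::str_detect(name1, stringr::fixed(syn)) |
      stringr::str_detect(name2, stringr::fixed(syn))
  }
  hit[is.na(hit)] <- FALSE
  if (cfg$require_primary_suspect) {
    hit <- hit & !is.na(drugs$role_cod) & drugs$role_cod == "PS"
  }
  cases$demo$primaryid %in% unique(drugs$primaryid[hit])
}

#' Screen case reports and split target from background
#'
#' Applies the screening pipeline in a fixed order: date-window filter
#' (on FDA receipt date), deduplication by case version, exclusion of
#' reports with all of sex/age/country/reporter missing (if enabled),
#' then the target/background split on the drug of interest. Every
#' removal is logged by reason and the log conserves counts:
#' input = target + background + removals.
#'
#' @param cases a `faers_cases` object (raw or already deduplicated;
#'   deduplication is applied internally either way).
#' @param cfg a [screening_config()].
#' @return A `screened_faers` object: list with `target` and
#'   `background` (`faers_cases`, disjoint), and `log` (tibble of
#'   `step`, `reason`, `count`).
#' @export
screen <- function(cases, cfg = screening_config()) {
  stopifnot(inherits(cases, "faers_cases"), inherits(cfg, "screening_config"))
  n_in <- nrow(cases$demo)
  log <- tibble::tibble(step = character(), reason = character(),
                        count = integer())

  lo <- quarter_start(cfg$date_window[1])
  hi <- quarter_end(cfg$date_window[2])
  in_window <- is.na(cases$demo$fda_dt) |
    (cases$demo$fda_dt >= lo & cases$demo$fda_dt <= hi)
  n_out <- sum(!in_window)
  cur <- filter_cases(cases, cases$demo$primaryid[in_window])
  log <- dplyr::add_row(log, step = "window", reason = "out_of_window",
                        count = as.integer(n_out))

  n_before <- nrow(cur$demo)
  cur <- deduplicate(cur)
  log <- dplyr::add_row(log, step = "deduplicate",
                        reason = "superseded_case_version",
                        count = as.integer(n_before - nrow(cur$demo)))

  if (cfg$exclude_missing_all_demographics) {
    d <- cur$demo
    all_missing <- is_missing_field(d$sex) & is.na(d$age) &
      is_missing_field(d$country) & is_missing_field(d$reporter)
    n_anon <- sum(all_missing)
    cur <- filter_cases(cur, d$primaryid[!all_missing])
    log <- dplyr::add_row(log, step = "missing_info",
                          reason = "all_demographics_missing",
                          count = as.integer(n_anon))
  }

  is_target <- match_target_drug(cur, cfg)
  target <- filter_cases(cur, cur$demo$primaryid[is_target])
  background <- filter_cases(cur, cur$demo$primaryid[!is_target])
  log <- dplyr::add_row(log, step = "split", reason = "target_reports",
                        count = as.integer(nrow(target$demo)))
  log <- dplyr::add_row(log, step = "split", reason = "background_reports",
                        count = as.integer(nrow(background$demo)))

  stopifnot(sum(log$count) == n_in)  # conservation
  structure(
    list(target = target, background = background, log = log, config = cfg),
    class = "screened_faers"
  )
}

# A categorical field counts as missing when NA, empty, or the UNK code.
is_missing_field <- function(x) {
  is.na(x) | !nzchar(trimws(as.character(x))) |
    toupper(trimws(as.character(x))) == "UNK"
}

#' @export
print.screened_faers <- function(x, ...) {
  cat("<screened_faers> target:", nrow(x$target$demo),
      "reports; background:", nrow(x$background$demo), "reports\n")
  invisible(x)
}

#' Annotate reactions with their system organ class
#'
#' Tags every reaction PT with its primary SOC from a [read_meddra_map()]
#' table. PTs absent from the map are tagged `soc_name = "UNMAPPED"`
#' (with `soc_code = NA`) and counted.
#'
#' @param x a `faers_cases` or `screened_faers` object.
#' @param map a `meddra_map` tibble.
#' @return The same object with `soc_name`, `soc_code` columns added to
#'   the reactions table(s); the unmapped count is reported via a
#'   message and recorded in the log attribute.
#' @export
annotate_soc <- function(x, map) {
  stopifnot(inherits(map, "meddra_map"))
  if (inherits(x, "screened_faers")) {
    x$target <- annotate_soc(x$target, map)
    x$background <- annotate_soc(x$background, map)
    return(x)
  }
  stopifnot(inherits(x, "faers_cases"))
  reac <- dplyr::left_join(x$reactions, map, by = "pt")
  unmapped <- is.na(reac$soc_name)
  reac$soc_name[unmapped] <- "UNMAPPED"
  if (any(unmapped)) {
    inform(sprintf("%d reaction occurrences have no SOC mapping",
                   sum(unmapped)))
  }
  x$reactions <- reac
  attr(x, "log") <- dplyr::bind_rows(
    attr(x, "log"),
    tibble::tibble(step = "annotate_soc", reason = "unmapped_pt_occurrences",
                   count = as.integer(sum(unmapped)))
  )
  x
}
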