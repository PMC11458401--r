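# Reading and writing FAERS-style quarterly tables, and assembly of raw
# rows into per-case records.

.demo_cols <- c("primaryid", "caseid", "caseversion", "event_dt", "age",
                "sex", "reporter", "country", "fda_dt")
.drug_cols <- c("primaryid", "drug_seq", "drugname", "prod_ai", "role_cod")
.reac_cols <- c("primaryid", "pt")
.outc_cols <- c("primaryid", "outc_cod")

#' Read one FAERS-style quarter
#'
#' Reads the four role tables of a quarterly extract (DEMO, DRUG, REAC,
#' OUTC) into a `faers_raw` object. Two dialects are supported: the
#' FAERS ASCII convention (`"faers_dollar"`, `'$'`-delimited with one
#' header line, dates as `YYYYMMDD`) and plain CSV for readable fixtures.
#' Unparseable dates and ages become missing values; rows are never
#' dropped at this stage.
#'
#' @param paths named list or character vector with elements `demo`,
#'   `drug`, `reac`, `outc` giving one file per table.
#' @param dialect `"faers_dollar"` (default) or `"csv"`.
#' @return A `faers_raw` object: a list of tibbles `demo`, `drug`,
#'   `reac`, `outc` with typed columns (`caseversion` integer, `age`
#'   numeric years, `event_dt`/`fda_dt` as `Date`).
#' @seealso [write_quarter()], [assemble_cases()]
#' @export
read_quarter <- function(paths, dialect = c("faers_dollar", "csv")) {
  dialect <- match.arg(dialect)
  need <- c("demo", "drug", "reac", "outc")
  if (!all(need %in% names(paths))) {
    abort(paste0("'paths' must name files for: ",
                 paste(setdiff(need, names(paths)), collapse = ", ")),
          class = "faersignal_format_error")
  }
  tabs <- list(
    demo = read_role_table(paths[["demo"]], .demo_cols, dialect),
    drug = read_role_table(paths[["drug"]], .drug_cols, dialect),
    reac = read_role_table(paths[["reac"]], .reac_cols, dialect),
    outc = read_role_table(paths[["outc"]], .outc_cols, dialect)
  )
  demo <- tabs$demo
  demo$caseversion <- {
    v <- parse_num(demo$caseversion)
    as.integer(ifelse(is.na(v), 1L, v))
  }
  demo$age <- parse_num(demo$age)
  demo$event_dt <- parse_faers_date(demo$event_dt)
  demo$fda_dt <- parse_faers_date(demo$fda_dt)
  drug <- tabs$drug
  drug$drug_seq <- as.integer(parse_num(drug$drug_seq))
  raw <- structure(
    list(demo = demo, drug = drug, reac = tabs$reac, outc = tabs$outc),
    class = "faers_raw"
  )
  inform(sprintf("read quarter: %d demo, %d drug, %d reac, %d outc rows",
                 nrow(demo), nrow(drug), nrow(tabs$reac), nrow(tabs$outc)))
  raw
}

read_role_table <- function(path, cols, dialect) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "faersignal_format_error")
  }
  delim <- if (dialect == "faers_dollar") "$" else ","
  tab <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE,
    locale = readr::locale(encoding = "UTF-8")
  )
  if (nrow(tab) == 0) {
    abort(paste0("empty table: ", path), class = "faersignal_format_error")
  }
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s) in ", basename(path), ": ",
                 paste(missing, collapse = ", ")),
          class = "faersignal_format_error")
  }
  tibble::as_tibble(tab[cols])
}

#' Write one FAERS-style quarter
#'
#' Inverse of [read_quarter()]: serializes a `faers_raw` object to the
#' four role tables. Round-trips all fields for the `faers_dollar`
#' dialect (dates as `YYYYMMDD`, missing values as empty fields).
#'
#' @param raw a `faers_raw` object.
#' @param dir output directory (created if absent).
#' @param dialect `"faers_dollar"` (default) or `"csv"`.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_quarter <- function(raw, dir, dialect = c("faers_dollar", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(raw, "faers_raw"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  delim <- if (dialect == "faers_dollar") "$" else ","
  ext <- if (dialect == "faers_dollar") "txt" else "csv"
  demo <- raw$demo
  demo$event_dt <- format_faers_date(demo$event_dt)
  demo$fda_dt <- format_faers_date(demo$fda_dt)
  paths <- c(
    demo = file.path(dir, paste0("demo.", ext)),
    drug = file.path(dir, paste0("drug.", ext)),
    reac = file.path(dir, paste0("reac.", ext)),
    outc = file.path(dir, paste0("outc.", ext))
  )
  readr::write_delim(demo, paths[["demo"]], delim = delim, na = "")
  readr::write_delim(raw$drug, paths[["drug"]], delim = delim, na = "")
  readr::write_delim(raw$reac, paths[["reac"]], delim = delim, na = "")
  readr::write_delim(raw$outc, paths[["outc"]], delim = delim, na = "")
  invisible(paths)
}

#' Assemble raw quarterly rows into per-case reports
#'
#' Joins the four role tables on `primaryid` into a `faers_cases`
#' object, one record per report. Orphan drug/reaction/outcome rows
#' (a `primaryid` absent from the DEMO table) are excluded and counted;
#' duplicate `(primaryid, pt)` reaction rows are collapsed to one with a
#' warning; reports with zero reactions are excluded and counted.
#'
#' @param raw a `faers_raw` object from [read_quarter()] or
#'   [generate_reports()].
#' @return A `faers_cases` object: list of tibbles `demo` (one row per
#'   report), `drugs`, `reactions`, `outcomes`, with an assembly log in
#'   `attr(, "log")` (columns `step`, `reason`, `count`).
#' @export
assemble_cases <- function(raw) {
  stopifnot(inherits(raw, "faers_raw"))
  ids <- raw$demo$primaryid
  log <- list()

  keep_drug <- raw$drug$primaryid %in% ids
  keep_reac <- raw$reac$primaryid %in% ids
  keep_outc <- raw$outc$primaryid %in% ids
  log[["orphan_drug_rows"]] <- sum(!keep_drug)
  log[["orphan_reac_rows"]] <- sum(!keep_reac)
  log[["orphan_outc_rows"]] <- sum(!keep_outc)

  reac <- raw$reac[keep_reac, ]
  reac$pt <- norm_term(reac$pt)
  n_before <- nrow(reac)
  reac <- dplyr::distinct(reac, .data$primaryid, .data$pt)
  n_collapsed <- n_before - nrow(reac)
  log[["collapsed_duplicate_reactions"]] <- n_collapsed
  if (n_collapsed > 0) {
    warn(sprintf("collapsed %d duplicate (primaryid, pt) reaction rows",
                 n_collapsed))
  }

  has_reac <- ids %in% reac$primaryid
  log[["reports_without_reactions"]] <- sum(!has_reac)
  demo <- raw$demo[has_reac, ]
  kept <- demo$primaryid

  out <- structure(
    list(
      demo = tibble::as_tibble(demo),
      drugs = dplyr::filter(raw$drug[keep_drug, ], .data$primaryid %in% kept),
      reactions = dplyr::filter(reac, .data$primaryid %in% kept),
      outcomes = dplyr::distinct(raw$outc[keep_outc, ]) |>
        dplyr::filter(.data$primaryid %in% kept)
    ),
    class = "faers_cases",
    log = tibble::tibble(
      step = "assemble",
      reason = names(log),
      count = as.integer(unlist(log))
    )
  )
  out
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases> ", nrow(x$demo), " reports, ",
      nrow(x$reactions), " reactions (",
      length(unique(x$reactions$pt)), " distinct PTs), ",
      nrow(x$drugs), " drug records\n", sep = "")
  invisible(x)
}

#' Number of case reports
#' @param x a `faers_cases` object.
#' @return Integer count of reports.
#' @export
n_cases <- function(x) {
  stopifnot(inherits(x, "faers_cases"))
  nrow(x$demo)
}

# Restrict a faers_cases object to a set of primaryids, preserving order
# of the demo table.
filter_cases <- function(x, keep_ids) {
  structure(
    list(
      demo = dplyr::filter(x$demo, .data$primaryid %in% keep_ids),
      drugs = dplyr::filter(x$drugs, .data$primaryid %in% keep_ids),
      reactions = dplyr::filter(x$reactions, .data$primaryid %in% keep_ids),
      outcomes = dplyr::filter(x$outcomes, .data$primaryid %in% keep_ids)
    ),
    class = "faers_cases",
    log = attr(x, "log")
  )
}

#' Read a PT-to-SOC mapping table
#'
#' Loads a user-supplied mapping from MedDRA preferred terms to their
#' primary system organ class. MedDRA content is licensed, so no mapping
#' is bundled; the expected CSV has columns `pt`, `soc_name`,
#' `soc_code`. Terms are normalized (trimmed, whitespace-squeezed,
#' case-folded) so lookup is case-insensitive.
#'
#' @param path CSV file path.
#' @return A `meddra_map` tibble with normalized `pt` plus `soc_name`,
#'   `soc_code`.
#' @export
read_meddra_map <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "faersignal_format_error")
  }
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(tab) == 0) {
    abort(paste0("empty mapping file: ", path),
          class = "faersignal_format_error")
  }
  missing <- setdiff(c("pt", "soc_name", "soc_code"), names(tab))
  if (length(missing) > 0) {
    abort(paste0("mapping file missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "faersignal_format_error")
  }
  tab <- tibble::as_tibble(tab[c("pt", "soc_name", "soc_code")])
  tab$pt <- norm_term(tab$pt)
  tab <- dplyr::distinct(tab)
  dup <- tab$pt[duplicated(tab$pt)]
  if (length(dup) > 0) {
    abort(paste0("PT(s) mapped to more than one SOC: ",
                 paste(unique(dup), collapse = ", ")),
          class = "faersignal_format_error")
  }
  class(tab) <- c("meddra_map", class(tab))
  tab
}
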