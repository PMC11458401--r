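# Descriptive characteristics of a report set and formatted signal
# tables ranked by EBGM.

#' Descriptive summary of case reports
#'
#' Counts and percentages per stratum for sex, age band (<18, 18-45,
#' 45-65, 65-75, >=75, Unknown), reporter type, country, report year
#' (FDA receipt date) and serious-outcome codes. Missing values fall in
#' the "Unknown" stratum. Percentages are `100 * count / total_reports`
#' rounded half-up to two decimals. Outcomes are counted per report and
#' a report may carry several outcome codes, so outcome strata need not
#' sum to the total.
#'
#' @param reports a `faers_cases` object (deduplicated).
#' @return A `descriptive_summary`: tibble with columns `factor`,
#'   `stratum`, `n`, `pct`, plus `attr(, "total_reports")`.
#' @export
describe <- function(reports) {
  stopifnot(inherits(reports, "faers_cases"))
  d <- reports$demo
  total <- nrow(d)

  strata <- function(fac, values, order = NULL) {
    values <- as.character(values)
    values[is.na(values) | !nzchar(trimws(values))] <- "Unknown"
    tab <- table(values)
    lev <- if (is.null(order)) {
      c(sort(setdiff(names(tab), "Unknown")),
        intersect("Unknown", names(tab)))
    } else {
      intersect(order, names(tab))
    }
    lev <- as.character(lev)
    tibble::tibble(factor = fac, stratum = lev,
                   n = as.integer(tab[lev]))
  }

  sex <- d$sex
  sex[!is.na(sex) & !(sex %in% c("F", "M"))] <- NA
  sex_lab <- c(F = "Female", M = "Male")[sex]

  band <- cut(d$age, breaks = c(-Inf, 18, 45, 65, 75, Inf), right = FALSE,
              labels = c("<18", "18-45", "45-65", "65-75", ">=75"))

  rep_lab <- tolower(trimws(as.character(d$reporter)))
  rep_lab[rep_lab %in% c("", "unk", "na")] <- NA
  rep_lab <- ifelse(is.na(rep_lab), NA,
                    paste0(toupper(substr(rep_lab, 1, 1)), substr(rep_lab, 2, nchar(rep_lab))))

  country <- norm_term(as.character(d$country))
  country[!nzchar(country)] <- NA

  year <- format(d$fda_dt, "%Y")

  parts <- list(
    strata("gender", sex_lab, order = c("Female", "Male", "Unknown")),
    strata("age", as.character(band),
           order = c("<18", "18-45", "45-65", "65-75", ">=75", "Unknown")),
    strata("reporter", rep_lab),
    dplyr::arrange(strata("country", country),
                   dplyr::desc(.data$n), .data$stratum),
    strata("report_year", year)
  )

  if (total > 0 && nrow(reports$outcomes) > 0) {
    oc <- dplyr::distinct(reports$outcomes, .data$primaryid, .data$outc_cod)
    ot <- dplyr::count(oc, .data$outc_cod, name = "n")
    parts <- c(parts, list(
      tibble::tibble(factor = "outcome", stratum = ot$outc_cod,
                     n = as.integer(ot$n)) |>
        dplyr::arrange(dplyr::desc(.data$n), .data$stratum)
    ))
  }

  out <- dplyr::bind_rows(parts)
  out$pct <- pct_of(out$n, total)
  class(out) <- c("descriptive_summary", class(out))
  attr(out, "total_reports") <- total
  out
}

fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' Formatted signal table ranked by EBGM
#'
#' Renders a scored signal set in the conventional published layout:
#' estimates with their 95% intervals as `"est (low-high)"`, two
#' decimals. At PT level only consensus signals (`pass_all`) are kept
#' and truncated to the strongest `top_n` by EBGM (ties broken by
#' `event_id`); at SOC level all organ classes are reported with their
#' scores.
#'
#' @param rows scored output of [score_all()].
#' @param top_n maximum rows for the PT-level table (default 30).
#' @param level `"PT"` or `"SOC"`.
#' @return Tibble with columns `event_id`, `n`, `ror_ci`, `prr_ci`,
#'   `chi2`, `ic_ic025`, `ebgm_ebgm05`.
#' @export
signal_report <- function(rows, top_n = 30L, level = c("PT", "SOC")) {
  level <- match.arg(level)
  if (!is.numeric(top_n) || length(top_n) != 1 || is.na(top_n) || top_n < 1) {
    abort("'top_n' must be a positive integer",
          class = "faersignal_config_error")
  }
  sel <- rows[rows$level == level, , drop = FALSE]
  if (level == "PT") sel <- sel[sel$pass_all, , drop = FALSE]
  sel <- dplyr::arrange(sel, dplyr::desc(.data$ebgm), .data$event_id)
  if (level == "PT") sel <- head(sel, as.integer(top_n))
  dash <- "\u2013"
  tibble::tibble(
    event_id = sel$event_id,
    n = sel$a,
    ror_ci = paste0(fmt2(sel$ror), " (", fmt2(sel$ror_low), dash,
                    fmt2(sel$ror_high), ")"),
    prr_ci = paste0(fmt2(sel$prr), " (", fmt2(sel$prr_low), dash,
                    fmt2(sel$prr_high), ")"),
    chi2 = fmt2(sel$chi2),
    ic_ic025 = paste0(fmt2(sel$ic), " (", fmt2(sel$ic025), ")"),
    ebgm_ebgm05 = paste0(fmt2(sel$ebgm), " (", fmt2(sel$ebgm05), ")")
  )
}

#' Published descriptive profile of capmatinib adverse-event reports
#'
#' Stratum counts of the 1,991 deduplicated FAERS reports with
#' capmatinib as primary suspect (2020Q2-2023Q4), as published:
#' gender, age bands, reporter type, top reporting countries, report
#' year, and serious-outcome counts. These counts serve as a worked
#' fixture for the descriptive summary: expanding them with
#' [profile_cases()] and running [describe()] must reproduce the
#' published percentages exactly.
#'
#' Note the published outcome labels are internally inconsistent for
#' the 313-count row (tabled as disability, described in prose as
#' hospitalization); here it is carried under code `HO` and the
#' 36-count row under `DS`.
#'
#' @return Named list of integer vectors plus `total`.
#' @export
capmatinib_profile <- function() {
  list(
    total = 1991L,
    gender = c(Female = 983L, Male = 791L, Unknown = 217L),
    age = c("<18" = 2L, "18-45" = 12L, "45-65" = 109L, "65-75" = 214L,
            ">=75" = 242L, Unknown = 1412L),
    reporter = c(Consumer = 1067L, Physician = 582L, Pharmacist = 268L,
                 Unknown = 74L),
    country = c("UNITED STATES" = 1245L, "FRANCE" = 86L, "JAPAN" = 41L,
                "NETHERLANDS" = 31L, "OTHER" = 588L),
    year = c("2020" = 200L, "2021" = 603L, "2022" = 642L, "2023" = 546L),
    outcomes = c(DE = 518L, HO = 313L, DS = 36L, LT = 29L)
  )
}

#' Expand a descriptive profile into case reports
#'
#' Deterministically constructs a `faers_cases` object whose marginal
#' stratum counts equal the given profile (factors are assigned
#' independently, block-wise, which preserves every single-factor
#' margin). Used to verify that [describe()] reproduces published
#' percentages from published counts.
#'
#' @param profile as returned by [capmatinib_profile()].
#' @return A `faers_cases` object with `profile$total` reports.
#' @export
profile_cases <- function(profile = capmatinib_profile()) {
  n <- profile$total
  fill <- function(counts) rep(names(counts), times = counts)
  sex <- c(Female = "F", Male = "M", Unknown = NA)[fill(profile$gender)]
  band_mid <- c("<18" = 10, "18-45" = 30, "45-65" = 55, "65-75" = 70,
                ">=75" = 80, Unknown = NA)
  age <- band_mid[fill(profile$age)]
  reporter <- fill(profile$reporter)
  reporter[reporter == "Unknown"] <- NA
  country <- fill(profile$country)
  year <- as.integer(fill(profile$year))
  fda_dt <- as.Date(sprintf("%d-07-01", year))
  fda_dt[year == 2020] <- as.Date("2020-10-01")
  ids <- sprintf("%07d1", seq_len(n))
  demo <- tibble::tibble(
    primaryid = ids, caseid = sprintf("%07d", seq_len(n)),
    caseversion = 1L, event_dt = fda_dt - 14L, age = unname(age),
    sex = unname(sex), reporter = tolower(reporter), country = country,
    fda_dt = fda_dt
  )
  oc <- profile$outcomes
  outcomes <- dplyr::bind_rows(lapply(names(oc), function(code) {
    tibble::tibble(primaryid = ids[seq_len(oc[[code]])], outc_cod = code)
  }))
  structure(
    list(
      demo = demo,
      drugs = tibble::tibble(primaryid = ids, drug_seq = 1L,
                             drugname = "TABRECTA", prod_ai = "CAPMATINIB",
                             role_cod = "PS"),
      reactions = tibble::tibble(primaryid = ids, pt = "ASTHENIA"),
      outcomes = outcomes
    ),
    class = "faers_cases",
    log = tibble::tibble(step = character(), reason = character(),
                         count = integer())
  )
}
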