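# Construction of the drug-event 2x2 ("four grid") tables:
#
#                    target event   other events   total
#   target drug           a              b          a+b
#   other drugs           c              d          c+d
#
# at preferred-term (PT) and system-organ-class (SOC) level.

#' Counting policy for contingency tables
#'
#' Under `unit = "pair"` (default) the counting unit is one
#' (report, PT) occurrence: a report with three distinct PTs contributes
#' three occurrences, and `N` is the total number of occurrences in the
#' corpus. This is the convention under which published SOC-level counts
#' can exceed the number of reports. Under `unit = "report"` the unit is
#' the report: `a` is the number of target reports carrying the event
#' and `N` the total number of reports.
#'
#' @param unit `"pair"` or `"report"`.
#' @return A `counting_policy` list.
#' @export
counting_policy <- function(unit = c("pair", "report")) {
  structure(list(unit = match.arg(unit)), class = "counting_policy")
}

#' Build PT-level contingency tables
#'
#' One 2x2 table per preferred term observed in the target reports. All
#' tables of a run share the margins: `a + b` is the total target count
#' and `c + d` the total background count at the chosen counting unit.
#'
#' @param data a `screened_faers` object from [screen()].
#' @param policy a [counting_policy()].
#' @return Tibble with columns `event_id`, `level` (`"PT"`), `a`, `b`,
#'   `c`, `d`, carrying the corpus total as `attr(, "N")` and the
#'   counting unit as `attr(, "unit")`.
#' @export
build_pt_tables <- function(data, policy = counting_policy()) {
  stopifnot(inherits(data, "screened_faers"), inherits(policy, "counting_policy"))
  build_tables(data, policy, level = "PT")
}

#' Build SOC-level contingency tables
#'
#' As [build_pt_tables()], but each (report, PT) occurrence is mapped to
#' its system organ class first, so a report with two PTs in one SOC
#' contributes twice to that SOC under pair counting (and once under
#' report counting). Occurrences with no SOC mapping (`UNMAPPED`) are
#' excluded and their count reported. Requires [annotate_soc()] to have
#' been applied.
#'
#' @inheritParams build_pt_tables
#' @return Tibble as in [build_pt_tables()] with `level = "SOC"` and
#'   `event_id` the SOC name; unmapped occurrence count in
#'   `attr(, "n_unmapped")`.
#' @export
build_soc_tables <- function(data, policy = counting_policy()) {
  stopifnot(inherits(data, "screened_faers"), inherits(policy, "counting_policy"))
  if (!"soc_name" %in% names(data$target$reactions)) {
    abort("reactions are not SOC-annotated; run annotate_soc() first",
          class = "faersignal_stage_error")
  }
  build_tables(data, policy, level = "SOC")
}

build_tables <- function(data, policy, level) {
  tgt <- data$target$reactions
  bkg <- data$background$reactions
  n_unmapped <- 0L
  if (level == "SOC") {
    n_unmapped <- sum(tgt$soc_name == "UNMAPPED") +
      sum(bkg$soc_name == "UNMAPPED")
    tgt <- tgt[tgt$soc_name != "UNMAPPED", ]
    bkg <- bkg[bkg$soc_name != "UNMAPPED", ]
    key <- "soc_name"
  } else {
    key <- "pt"
  }
  if (nrow(tgt) == 0) {
    warn("no target reactions; returning empty table set")
    out <- tibble::tibble(event_id = character(), level = character(),
                          a = integer(), b = integer(),
                          c = integer(), d = integer())
    attr(out, "N") <- 0L
    attr(out, "unit") <- policy$unit
    return(out)
  }

  if (policy$unit == "report") {
    # one count per report per distinct event
    tgt <- dplyr::distinct(tgt[c("primaryid", key)])
    bkg <- dplyr::distinct(bkg[c("primaryid", key)])
    tot_t <- nrow(data$target$demo)
    tot_b <- nrow(data$background$demo)
    cnt_t <- dplyr::count(tgt, .data[[key]], name = "a")
    cnt_b <- dplyr::count(bkg, .data[[key]], name = "c")
  } else {
    # pair occurrences: reactions tables already hold one row per
    # (report, PT); at SOC level each mapped occurrence counts
    tot_t <- nrow(tgt)
    tot_b <- nrow(bkg)
    cnt_t <- dplyr::count(tgt, .data[[key]], name = "a")
    cnt_b <- dplyr::count(bkg, .data[[key]], name = "c")
  }

  out <- dplyr::left_join(cnt_t, cnt_b, by = key)
  out$c[is.na(out$c)] <- 0L
  out <- tibble::tibble(
    event_id = out[[key]],
    level = level,
    a = as.integer(out$a),
    b = as.integer(tot_t - out$a),
    c = as.integer(out$c),
    d = as.integer(tot_b - out$c)
  )
  out <- dplyr::arrange(out, .data$event_id)
  attr(out, "N") <- as.integer(tot_t + tot_b)
  attr(out, "unit") <- policy$unit
  if (level == "SOC") attr(out, "n_unmapped") <- as.integer(n_unmapped)
  out
}
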