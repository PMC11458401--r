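# Compact constructors for hand-built case sets.

# reports: list of lists with fields
#   id (primaryid), caseid, version, fda, sex, age, country, reporter,
#   drugs  = list(c(name, role)), pts = character vector,
#   outc = character vector
make_cases <- function(reports) {
  demo <- dplyr::bind_rows(lapply(reports, function(r) {
    tibble::tibble(
      primaryid = r$id,
      caseid = r$caseid %||% r$id,
      caseversion = as.integer(r$version %||% 1L),
      event_dt = as.Date(r$event %||% NA),
      age = r$age %||% NA_real_,
      sex = r$sex %||% NA_character_,
      reporter = r$reporter %||% NA_character_,
      country = r$country %||% NA_character_,
      fda_dt = as.Date(r$fda %||% "2022-06-15")
    )
  }))
  drugs <- dplyr::bind_rows(lapply(reports, function(r) {
    dl <- r$drugs %||% list(c("TABRECTA", "PS"))
    tibble::tibble(
      primaryid = r$id,
      drug_seq = seq_along(dl),
      drugname = vapply(dl, `[`, "", 1),
      prod_ai = NA_character_,
      role_cod = vapply(dl, `[`, "", 2)
    )
  }))
  reactions <- dplyr::bind_rows(lapply(reports, function(r) {
    tibble::tibble(primaryid = r$id, pt = r$pts %||% "AE_TERM_001")
  }))
  outcomes <- dplyr::bind_rows(lapply(reports, function(r) {
    if (is.null(r$outc)) return(NULL)
    tibble::tibble(primaryid = r$id, outc_cod = r$outc)
  }))
  if (nrow(outcomes %||% tibble::tibble()) == 0) {
    outcomes <- tibble::tibble(primaryid = character(),
                               outc_cod = character())
  }
  structure(
    list(demo = demo, drugs = drugs, reactions = reactions,
         outcomes = outcomes),
    class = "faers_cases",
    log = tibble::tibble(step = character(), reason = character(),
                         count = integer())
  )
}

# Directly build a screened dataset from two case sets.
make_screened <- function(target, background) {
  structure(
    list(target = target, background = background,
         log = tibble::tibble(step = character(), reason = character(),
                              count = integer()),
         config = screening_config()),
    class = "screened_faers"
  )
}

`%||%` <- rlang::`%||%`

# Run the standard pipeline (assemble -> screen -> PT tables -> scores)
# on a generated dataset; returns the scored PT signal table.
pipeline_scores <- function(gen, cfg_screen = screening_config(),
                            policy = counting_policy()) {
  cases <- suppressWarnings(assemble_cases(gen$raw))
  scr <- screen(cases, cfg_screen)
  tabs <- build_pt_tables(scr, policy)
  score_all(tabs)
}
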