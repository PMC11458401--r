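# End-to-end pipeline driver: ingest -> screen -> contingency -> score
# -> describe -> report, configured from a YAML file.

#' Run the full signal-mining pipeline from a config file
#'
#' Executes ingest, screening, contingency-table construction, signal
#' scoring, descriptive summary and report formatting, writing all
#' outputs as CSV plus a run-metadata JSON and a plain-text log. Outputs
#' are deterministic: the same configuration (including any simulation
#' seed) produces byte-identical files.
#'
#' The YAML configuration has sections:
#' \describe{
#'   \item{`input`}{either `simulate:` (arguments for [sim_config()],
#'     e.g. `seed`, `n_target_reports`, `planted_signals` as a list of
#'     `{pt, rr}`) or `quarter:` with file paths `demo`, `drug`, `reac`,
#'     `outc` and optional `dialect`.}
#'   \item{`meddra_map`}{path to the PT-to-SOC CSV; optional for
#'     simulated input, where the generator's catalog map is used.}
#'   \item{`screening`}{arguments for [screening_config()].}
#'   \item{`thresholds`}{arguments for [signal_thresholds()].}
#'   \item{`priors`}{arguments for [bcpnn_priors()].}
#'   \item{`counting`}{`unit: pair` (default) or `report`.}
#'   \item{`report`}{`top_n` (default 30).}
#'   \item{`out_dir`}{output directory.}
#' }
#'
#' @param config_path path to the YAML configuration.
#' @param out_dir optional override of the configured output directory.
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  cfg <- yaml::read_yaml(config_path)
  out_dir <- out_dir %||% cfg$out_dir %||%
    stage_abort("config", "no output directory configured")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  # --- ingest ---------------------------------------------------------
  ing <- with_stage("ingest", {
    if (!is.null(cfg$input$simulate)) {
      sim <- do.call(sim_config, normalize_sim_args(cfg$input$simulate))
      gen <- generate_reports(sim)
      say("ingest: simulated %d target + %d background unique cases (seed %d)",
          sim$n_target_reports, sim$n_background_reports, sim$seed)
      gen[c("raw", "truth")]
    } else if (!is.null(cfg$input$quarter)) {
      q <- cfg$input$quarter
      dialect <- q$dialect %||% "faers_dollar"
      say("ingest: reading quarter tables (%s dialect)", dialect)
      list(raw = suppressMessages(read_quarter(q, dialect = dialect)),
           truth = NULL)
    } else {
      stage_abort("ingest", "config must provide input$simulate or input$quarter")
    }
  })
  raw <- ing$raw
  truth <- ing$truth
  cases <- with_stage("assemble", suppressWarnings(assemble_cases(raw)))
  say("assemble: %d reports with reactions", nrow(cases$demo))

  # --- screen ---------------------------------------------------------
  scr_cfg <- with_stage("screen",
                        do.call(screening_config, as.list(cfg$screening %||% list())))
  screened <- with_stage("screen", screen(cases, scr_cfg))
  say("screen: %d target, %d background reports",
      nrow(screened$target$demo), nrow(screened$background$demo))

  # --- annotate -------------------------------------------------------
  map <- with_stage("annotate", {
    if (!is.null(cfg$meddra_map)) {
      read_meddra_map(cfg$meddra_map)
    } else if (!is.null(truth)) {
      truth_meddra_map(truth)
    } else {
      stage_abort("annotate", "no meddra_map configured and input is not simulated")
    }
  })
  screened <- with_stage("annotate", suppressMessages(annotate_soc(screened, map)))

  # --- contingency ----------------------------------------------------
  policy <- counting_policy(cfg$counting$unit %||% "pair")
  tab_pt <- with_stage("contingency", build_pt_tables(screened, policy))
  tab_soc <- with_stage("contingency", build_soc_tables(screened, policy))
  say("contingency: %d PT tables, %d SOC tables (unit=%s, N=%d)",
      nrow(tab_pt), nrow(tab_soc), policy$unit, attr(tab_pt, "N"))

  # --- score ----------------------------------------------------------
  priors <- with_stage("score", do.call(bcpnn_priors, as.list(cfg$priors %||% list())))
  th_args <- as.list(cfg$thresholds %||% list())
  if (is.null(th_args$min_a)) th_args$min_a <- scr_cfg$min_pair_count
  th <- with_stage("score", do.call(signal_thresholds, th_args))
  sig_pt <- with_stage("score", score_all(tab_pt, priors, th))
  sig_soc <- with_stage("score", score_all(tab_soc, priors, th))
  say("score: %d consensus PT signals of %d pairs",
      sum(sig_pt$pass_all), nrow(sig_pt))

  # --- describe & report ---------------------------------------------
  desc <- with_stage("describe", describe(screened$target))
  top_n <- cfg$report$top_n %||% 30L
  rep_pt <- with_stage("report", signal_report(sig_pt, top_n = top_n, level = "PT"))
  rep_soc <- with_stage("report", signal_report(sig_soc, top_n = top_n, level = "SOC"))

  # --- outputs --------------------------------------------------------
  wr <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, name))
  }
  wr(screened$log, "screening_log.csv")
  wr(tab_pt, "contingency_pt.csv")
  wr(tab_soc, "contingency_soc.csv")
  wr(sig_pt, "signals_pt.csv")
  wr(sig_soc, "signals_soc.csv")
  wr(tibble::as_tibble(desc), "descriptive.csv")
  wr(rep_pt, "report_pt.csv")
  wr(rep_soc, "report_soc.csv")
  meta <- list(
    package = "faersignal",
    version = as.character(utils::packageVersion("faersignal")),
    counting_unit = policy$unit,
    n_total = attr(tab_pt, "N"),
    priors = unclass(priors),
    thresholds = unclass(th),
    screening = unclass(scr_cfg),
    ebgm_note = paste("EBGM is the closed-form observed/expected ratio",
                      "a*N/((a+b)(a+c)), not a fitted gamma-Poisson mixture;",
                      "IC uses the Bate-style variance with IC025 = E(IC) - 2*SD."),
    config = cfg
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

# YAML gives lists; coerce the sim-config arguments it may carry.
normalize_sim_args <- function(args) {
  args <- as.list(args)
  if (!is.null(args$planted_signals)) {
    ps <- args$planted_signals
    if (is.list(ps) && !is.data.frame(ps)) {
      args$planted_signals <- tibble::tibble(
        pt = vapply(ps, function(x) as.character(x$pt), character(1)),
        rr = vapply(ps, function(x) as.numeric(x$rr), numeric(1))
      )
    }
  }
  if (!is.null(args$missing_rates)) {
    args$missing_rates <- unlist(args$missing_rates)
  }
  args
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "faersignal_stage_abort")) stop(e)
    abort(sprintf("pipeline aborted at stage '%s': %s", stage,
                  conditionMessage(e)),
          class = c("faersignal_stage_abort", "faersignal_stage_error"),
          stage = stage)
  })
}

stage_abort <- function(stage, msg) {
  abort(sprintf("pipeline aborted at stage '%s': %s", stage, msg),
        class = c("faersignal_stage_abort", "faersignal_stage_error"),
        stage = stage)
}
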