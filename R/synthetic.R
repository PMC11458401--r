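# Synthetic spontaneous-report generator. Emulates the structure of
# FAERS quarterly extracts -- per-case drug records with role codes,
# multiple reaction PTs per case, case versioning (duplicates), missing
# demographics, reporter/country/outcome strata -- with known ground
# truth: planted drug-event relative risks and per-pair occurrence
# counts, so every pipeline stage can be checked against an independent
# count.

#' Default synthetic PT catalog
#'
#' A catalog of `n_pt` preferred terms spread evenly over `n_soc`
#' system organ classes, each with the same background reporting
#' probability. With 100 PTs at probability 0.02 a report carries on
#' average 2 PTs (Poisson-binomial; a minimum of 1 is enforced at
#' generation time).
#'
#' @param n_pt number of preferred terms (default 100).
#' @param n_soc number of organ classes (default 20).
#' @param background_prob per-report probability of each PT (default 0.02).
#' @return Tibble with columns `pt`, `soc`, `soc_code`,
#'   `background_prob`.
#' @export
default_pt_catalog <- function(n_pt = 100L, n_soc = 20L,
                               background_prob = 0.02) {
  soc_idx <- ((seq_len(n_pt) - 1L) %% n_soc) + 1L
  tibble::tibble(
    pt = sprintf("AE_TERM_%03d", seq_len(n_pt)),
    soc = sprintf("SOC_%02d", soc_idx),
    soc_code = sprintf("100%05d", soc_idx),
    background_prob = background_prob
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic report generator. Defaults emulate the
#' descriptive strata of published capmatinib FAERS reports (sex,
#' age-band, reporter, country, report-year and serious-outcome
#' proportions) and a corpus of equally sized target and background
#' arms. Signals are planted multiplicatively: an exposed (target)
#' report draws a planted PT with probability
#' `min(1, background_prob * rr)`, which makes the planted relative
#' risk the estimand that disproportionality statistics target.
#'
#' @param n_target_reports,n_background_reports arm sizes (default
#'   20000 each).
#' @param pt_catalog tibble as from [default_pt_catalog()].
#' @param planted_signals `NULL`, or tibble with columns `pt`, `rr`
#'   (relative risk >= 0) for PTs in the catalog.
#' @param duplicate_rate probability that a case is re-emitted as a
#'   second, superseding version (default 0.1).
#' @param missing_rates named numeric vector of extra missingness
#'   probabilities for fields `sex`, `age`, `country`, `reporter`,
#'   `event_date` (defaults 0; "Unknown" strata already arise from
#'   `demographic_probs`).
#' @param demographic_probs named list of categorical distributions:
#'   `sex`, `age_stratum`, `reporter`, `country`, `year` (probabilities
#'   summing to 1) and `outcomes` (independent per-report probabilities
#'   per outcome code, need not sum to 1).
#' @param seed integer; all randomness flows from it — the same config
#'   yields byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_target_reports = 20000L,
                       n_background_reports = 20000L,
                       pt_catalog = default_pt_catalog(),
                       planted_signals = NULL,
                       duplicate_rate = 0.1,
                       missing_rates = c(sex = 0, age = 0, country = 0,
                                         reporter = 0, event_date = 0),
                       demographic_probs = default_demographic_probs(),
                       seed = 1L) {
  stopifnot_scalar_count(n_target_reports, "n_target_reports")
  stopifnot_scalar_count(n_background_reports, "n_background_reports")
  if (anyDuplicated(pt_catalog$pt)) {
    abort("pt_catalog PTs must be unique", class = "faersignal_config_error")
  }
  if (any(pt_catalog$background_prob < 0 | pt_catalog$background_prob > 1)) {
    abort("background_prob values must lie in [0, 1]",
          class = "faersignal_config_error")
  }
  if (all(pt_catalog$background_prob == 0)) {
    abort("infeasible catalog: all background probabilities are zero",
          class = "faersignal_config_error")
  }
  if (!is.null(planted_signals)) {
    planted_signals <- tibble::as_tibble(planted_signals)
    stopifnot(all(c("pt", "rr") %in% names(planted_signals)))
    if (any(!planted_signals$pt %in% pt_catalog$pt)) {
      abort("planted_signals reference PTs absent from the catalog",
            class = "faersignal_config_error")
    }
    if (any(planted_signals$rr < 0)) {
      abort("planted relative risks must be >= 0",
            class = "faersignal_config_error")
    }
  }
  mr <- c(sex = 0, age = 0, country = 0, reporter = 0, event_date = 0)
  mr[names(missing_rates)] <- missing_rates
  if (any(mr < 0 | mr > 1) || duplicate_rate < 0 || duplicate_rate > 1) {
    abort("rates must be probabilities in [0, 1]",
          class = "faersignal_config_error")
  }
  for (f in c("sex", "age_stratum", "reporter", "country", "year")) {
    p <- demographic_probs[[f]]
    if (abs(sum(p) - 1) > 1e-8) {
      abort(paste0("demographic_probs$", f, " must sum to 1"),
            class = "faersignal_config_error")
    }
  }
  structure(
    list(
      n_target_reports = as.integer(n_target_reports),
      n_background_reports = as.integer(n_background_reports),
      pt_catalog = tibble::as_tibble(pt_catalog),
      planted_signals = planted_signals,
      duplicate_rate = duplicate_rate,
      missing_rates = mr,
      demographic_probs = demographic_probs,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default demographic stratum probabilities
#'
#' Mirrors the published descriptive profile of capmatinib FAERS
#' reports: sex (female 0.4937), reporter (consumer 0.5359), country
#' (United States 0.6253), age bands (unknown 0.7092), report year, and
#' per-report serious-outcome probabilities (death 0.2602,
#' hospitalization 0.1572, disability 0.0181, life-threatening 0.0146).
#'
#' @return Named list of probability vectors.
#' @export
default_demographic_probs <- function() {
  list(
    sex = c(F = 0.4937, M = 0.3973, UNK = 0.1090),
    age_stratum = c("<18" = 0.0010, "18-45" = 0.0060, "45-65" = 0.0547,
                    "65-75" = 0.1075, ">=75" = 0.1216, Unknown = 0.7092),
    reporter = c(consumer = 0.5359, physician = 0.2923,
                 pharmacist = 0.1346, UNK = 0.0372),
    country = c("UNITED STATES" = 0.6253, "FRANCE" = 0.0432,
                "JAPAN" = 0.0206, "NETHERLANDS" = 0.0156,
                "OTHER" = 0.2953),
    year = c("2020" = 0.1005, "2021" = 0.3029, "2022" = 0.3225,
             "2023" = 0.2741),
    outcomes = c(DE = 0.2602, HO = 0.1572, DS = 0.0181, LT = 0.0146)
  )
}

.age_band_range <- list("<18" = c(1, 17), "18-45" = c(18, 44),
                        "45-65" = c(45, 64), "65-75" = c(65, 74),
                        ">=75" = c(75, 95))

#' Generate a synthetic FAERS-style quarter with ground truth
#'
#' Draws `n_target + n_background` unique case reports. Target reports
#' carry the target drug (role `PS`); all reports draw each catalog PT
#' independently with probability `background_prob` (times the planted
#' relative risk for exposed reports), with at least one PT enforced
#' per report. A fraction `duplicate_rate` of cases is re-emitted as a
#' superseding second version (same content, later FDA date, higher
#' `caseversion`). All randomness is derived from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param dir optional directory; when given, the quarter is also
#'   written as `'$'`-delimited files via [write_quarter()] and the
#'   catalog's PT-to-SOC map as `meddra_map.csv`.
#' @return List with elements `raw` (a `faers_raw`), `truth` (a
#'   `synthetic_truth`), and `files` (paths, or `NULL`).
#' @export
generate_reports <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, generate_reports_impl(cfg, dir))
}

generate_reports_impl <- function(cfg, dir) {
  nt <- cfg$n_target_reports
  nb <- cfg$n_background_reports
  n <- nt + nb
  exposed <- c(rep(TRUE, nt), rep(FALSE, nb))
  catalog <- cfg$pt_catalog
  npt <- nrow(catalog)
  dp <- cfg$demographic_probs

  # --- reaction draws -------------------------------------------------
  p <- matrix(rep(catalog$background_prob, each = n), nrow = n)
  if (!is.null(cfg$planted_signals) && nrow(cfg$planted_signals) > 0 && nt > 0) {
    for (k in seq_len(nrow(cfg$planted_signals))) {
      j <- match(cfg$planted_signals$pt[k], catalog$pt)
      p[exposed, j] <- pmin(1, p[exposed, j] * cfg$planted_signals$rr[k])
    }
  }
  draws <- matrix(runif(n * npt), nrow = n) < p
  empty <- which(rowSums(draws) == 0)
  for (i in empty) {
    draws[i, sample.int(npt, 1L, prob = p[i, ] + 1e-12)] <- TRUE
  }
  hit <- which(draws, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]

  # --- demographics ---------------------------------------------------
  caseid <- as.character(10000000L + seq_len(n))
  sex <- sample(names(dp$sex), n, TRUE, dp$sex)
  sex[sex == "UNK"] <- NA_character_
  band <- sample(names(dp$age_stratum), n, TRUE, dp$age_stratum)
  age <- rep(NA_real_, n)
  for (bn in names(.age_band_range)) {
    idx <- which(band == bn)
    r <- .age_band_range[[bn]]
    age[idx] <- floor(runif(length(idx), r[1], r[2] + 1))
  }
  reporter <- sample(names(dp$reporter), n, TRUE, dp$reporter)
  reporter[reporter == "UNK"] <- NA_character_
  country <- sample(names(dp$country), n, TRUE, dp$country)
  year <- as.integer(sample(names(dp$year), n, TRUE, dp$year))
  qtr <- integer(n)
  qtr[year == 2020] <- sample(2:4, sum(year == 2020), TRUE)
  qtr[year != 2020] <- sample(1:4, sum(year != 2020), TRUE)
  qs <- quarter_start_v(year, qtr)
  qlen <- as.integer(quarter_end_v(year, qtr) - qs) + 1L
  fda_dt <- qs + floor(runif(n) * qlen)
  event_dt <- fda_dt - floor(runif(n, 0, 61))

  # extra planted missingness on top of the Unknown strata
  mr <- cfg$missing_rates
  miss <- list(
    sex = runif(n) < mr[["sex"]],
    age = runif(n) < mr[["age"]],
    country = runif(n) < mr[["country"]],
    reporter = runif(n) < mr[["reporter"]],
    event_date = runif(n) < mr[["event_date"]]
  )
  sex[miss$sex] <- NA_character_
  age[miss$age] <- NA_real_
  country[miss$country] <- NA_character_
  reporter[miss$reporter] <- NA_character_
  event_dt[miss$event_date] <- as.Date(NA)

  # --- outcomes -------------------------------------------------------
  oc <- dp$outcomes
  outc_list <- lapply(names(oc), function(code) {
    has <- which(runif(n) < oc[[code]])
    data.frame(case_idx = has, outc_cod = rep(code, length(has)))
  })
  outc_idx <- do.call(rbind, outc_list)
  outc_idx <- outc_idx[order(outc_idx$case_idx), , drop = FALSE]

  # --- drug records ---------------------------------------------------
  target_names <- c("TABRECTA", "CAPMATINIB", "TABRECTA 400MG TABLET")
  bg_drugs <- sprintf("DRUG_%03d", 1:50)
  ps_name <- character(n)
  ps_name[exposed] <- sample(target_names, nt, TRUE)
  ps_name[!exposed] <- sample(bg_drugs, nb, TRUE)
  ps_ai <- ifelse(exposed, "CAPMATINIB", NA_character_)
  n_con <- sample(0:2, n, TRUE)
  con_case <- rep(seq_len(n), n_con)
  con_rows <- data.frame(
    case_idx = con_case,
    drug_seq = unlist(lapply(n_con[n_con > 0], seq_len), use.names = FALSE) + 1L,
    drugname = sample(bg_drugs, length(con_case), TRUE),
    prod_ai = NA_character_,
    role_cod = sample(c("SS", "C", "I"), length(con_case), TRUE)
  )
  drug_idx <- rbind(
    data.frame(case_idx = seq_len(n), drug_seq = 1L, drugname = ps_name,
               prod_ai = ps_ai, role_cod = "PS"),
    con_rows
  )
  drug_idx <- drug_idx[order(drug_idx$case_idx, drug_idx$drug_seq), , drop = FALSE]

  # --- duplicates (case versioning) ----------------------------------
  dup <- runif(n) < cfg$duplicate_rate

  mk_primary <- function(idx, version) {
    if (length(idx) == 0) return(character(0))
    paste0(caseid[idx], version)
  }
  demo_of <- function(idx, version, date_shift = 0L) {
    tibble::tibble(
      primaryid = mk_primary(idx, version),
      caseid = caseid[idx],
      caseversion = version,
      event_dt = event_dt[idx],
      age = age[idx],
      sex = sex[idx],
      reporter = reporter[idx],
      country = country[idx],
      fda_dt = fda_dt[idx] + date_shift
    )
  }
  rows_of <- function(tab, idx_col, keep_idx, version) {
    sel <- tab[tab[[idx_col]] %in% keep_idx, , drop = FALSE]
    sel$primaryid <- mk_primary(sel[[idx_col]], version)
    sel
  }

  all_idx <- seq_len(n)
  dup_idx <- which(dup)
  demo <- dplyr::bind_rows(demo_of(all_idx, 1L),
                           demo_of(dup_idx, 2L, date_shift = 30L))
  reac_tab <- data.frame(case_idx = hit[, 1], pt = catalog$pt[hit[, 2]])
  reac <- dplyr::bind_rows(
    rows_of(reac_tab, "case_idx", all_idx, 1L),
    rows_of(reac_tab, "case_idx", dup_idx, 2L)
  )[c("primaryid", "pt")]
  drug <- dplyr::bind_rows(
    rows_of(drug_idx, "case_idx", all_idx, 1L),
    rows_of(drug_idx, "case_idx", dup_idx, 2L)
  )[c("primaryid", "drug_seq", "drugname", "prod_ai", "role_cod")]
  outc <- dplyr::bind_rows(
    rows_of(outc_idx, "case_idx", all_idx, 1L),
    rows_of(outc_idx, "case_idx", dup_idx, 2L)
  )[c("primaryid", "outc_cod")]

  raw <- structure(
    list(demo = demo, drug = tibble::as_tibble(drug),
         reac = tibble::as_tibble(reac), outc = tibble::as_tibble(outc)),
    class = "faers_raw"
  )

  # --- ground truth ---------------------------------------------------
  n_t_pt <- if (nt > 0) colSums(draws[exposed, , drop = FALSE]) else rep(0L, npt)
  n_b_pt <- if (nb > 0) colSums(draws[!exposed, , drop = FALSE]) else rep(0L, npt)
  truth <- structure(
    list(
      case_truth = tibble::tibble(
        caseid = caseid, exposed = exposed, n_versions = 1L + dup,
        miss_sex = miss$sex | is.na(sex), miss_age = is.na(age),
        miss_country = is.na(country), miss_reporter = is.na(reporter)
      ),
      pair_counts = tibble::tibble(
        pt = catalog$pt, soc = catalog$soc,
        n_target = as.integer(n_t_pt), n_background = as.integer(n_b_pt)
      ),
      planted = cfg$planted_signals,
      catalog = catalog,
      n_unique_cases = n,
      n_duplicate_rows = as.integer(sum(dup)),
      config = cfg
    ),
    class = "synthetic_truth"
  )

  files <- NULL
  if (!is.null(dir)) {
    files <- write_quarter(raw, dir)
    map_path <- file.path(dir, "meddra_map.csv")
    readr::write_csv(
      tibble::tibble(pt = catalog$pt, soc_name = catalog$soc,
                     soc_code = catalog$soc_code),
      map_path
    )
    files <- c(files, meddra_map = map_path)
  }
  list(raw = raw, truth = truth, files = files)
}

quarter_start_v <- function(year, qtr) {
  as.Date(sprintf("%d-%02d-01", year, (qtr - 1L) * 3L + 1L))
}
quarter_end_v <- function(year, qtr) {
  nxt <- ifelse(qtr == 4L, sprintf("%d-01-01", year + 1L),
                sprintf("%d-%02d-01", year, qtr * 3L + 1L))
  as.Date(nxt) - 1L
}

#' The PT-to-SOC map implied by a synthetic catalog
#'
#' @param truth a `synthetic_truth` (or a `sim_config`).
#' @return A `meddra_map` tibble usable with [annotate_soc()].
#' @export
truth_meddra_map <- function(truth) {
  catalog <- if (inherits(truth, "synthetic_truth")) truth$catalog else truth$pt_catalog
  map <- tibble::tibble(pt = norm_term(catalog$pt), soc_name = catalog$soc,
                        soc_code = catalog$soc_code)
  class(map) <- c("meddra_map", class(map))
  map
}

#' Contingency tables computed directly from generator truth
#'
#' An independent counting path: builds the 2x2 tables from the
#' generator's per-pair occurrence counts (recorded at draw time, before
#' any serialization, duplication or screening), bypassing the pipeline
#' entirely. Used as the oracle for the contingency module. Counts are
#' per unique case and pair occurrence, so they equal the pipeline's
#' tables on a fully screened, deduplicated dataset.
#'
#' @param truth a `synthetic_truth` from [generate_reports()].
#' @param level `"PT"` or `"SOC"`.
#' @return Tibble with columns `event_id`, `level`, `a`, `b`, `c`, `d`,
#'   restricted to events observed in the target arm.
#' @export
truth_tables <- function(truth, level = c("PT", "SOC")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  level <- match.arg(level)
  pc <- truth$pair_counts
  if (level == "SOC") {
    a_vec <- tapply(pc$n_target, pc$soc, sum)
    c_vec <- tapply(pc$n_background, pc$soc, sum)
    ids <- names(a_vec)
  } else {
    a_vec <- setNames(pc$n_target, pc$pt)
    c_vec <- setNames(pc$n_background, pc$pt)
    ids <- pc$pt
  }
  tot_t <- sum(pc$n_target)
  tot_b <- sum(pc$n_background)
  keep <- a_vec > 0
  out <- tibble::tibble(
    event_id = ids[keep],
    level = level,
    a = as.integer(a_vec[keep]),
    b = as.integer(tot_t - a_vec[keep]),
    c = as.integer(c_vec[keep]),
    d = as.integer(tot_b - c_vec[keep])
  )
  out <- out[order(out$event_id), ]
  attr(out, "N") <- as.integer(tot_t + tot_b)
  attr(out, "unit") <- "pair"
  out
}
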