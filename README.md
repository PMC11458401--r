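# faersignal

Disproportionality signal mining for spontaneous adverse-event
reports, for pharmacovigilance analysts and methodologists working
with FAERS-style data. The package implements the complete pipeline
used in published FAERS safety studies — the motivating case is
capmatinib (Tabrecta), a selective MET inhibitor for *MET*
exon-14-skipping non-small-cell lung cancer — and a synthetic
report generator with planted ground truth so the whole pipeline can
be validated offline.

## What it computes

For each drug–event pair the four-grid

|              | target event | other events |
|--------------|--------------|--------------|
| target drug  | a            | b            |
| other drugs  | c            | d            |

is built at MedDRA preferred-term (PT) and system-organ-class (SOC)
level, and scored with:

* **ROR** = ad/bc with the Woolf 95% CI; signal if a ≥ 3 and CI lower
  limit > 1
* **PRR** = [a/(a+b)]/[c/(c+d)] with its 95% CI; same rule
* **Pearson χ²** (Yates-corrected by default)
* **BCPNN IC** — E(IC) and IC025 = E(IC) − 2·SD under the canonical
  Beta priors; signal if IC025 > 0
* **EBGM** = aN/((a+b)(a+c)) (observed/expected closed form) with
  EBGM05; signal if EBGM05 > 2

plus the all-four consensus flag, with results ranked by EBGM.
Upstream of the statistics: `$`-delimited quarterly table I/O,
case-version deduplication, drug-name synonym matching with the
primary-suspect restriction, date-window and missing-information
screening (all removals logged by reason), and user-supplied PT→SOC
annotation (MedDRA is licensed and not bundled).

## Worked example

Simulate a corpus in the sparse-target regime (5,000 target vs 100,000
background reports) with one planted signal at relative risk 8, then
run the pipeline:

```r
library(faersignal)

cfg <- sim_config(
  n_target_reports = 5000, n_background_reports = 100000,
  planted_signals = tibble::tibble(pt = "AE_TERM_042", rr = 8),
  seed = 2024)
gen   <- generate_reports(cfg)
cases <- assemble_cases(gen$raw)
scr   <- annotate_soc(screen(cases), truth_meddra_map(gen$truth))
sig   <- score_all(build_pt_tables(scr))
signal_report(sig, top_n = 5)
#> # A tibble: 1 × 7
#>   event_id        n ror_ci           prr_ci           chi2    ic_ic025    ebgm_ebgm05
#>   <chr>       <int> <chr>            <chr>            <chr>   <chr>       <chr>
#> 1 AE_TERM_042   844 8.20 (7.55–8.91) 7.66 (7.09–8.28) 3530.51 2.52 (2.40) 5.75 (5.30)
```

The planted pair is the only consensus signal: 844 of 5,000 target
reports carry the event, the ROR point estimate 8.20 recovers the
planted relative risk 8, and every interval lower limit clears its
threshold. (EBGM reads lower, 5.75 — it is observed/expected against
pooled margins, which the signal itself inflates; the bias grows with
the target drug's share of the corpus and is discussed in the
vignette.) Descriptive strata mirror published capmatinib report
demographics by default:

```r
head(describe(scr$target), 3)
#> # A tibble: 3 × 4
#>   factor stratum     n   pct
#> 1 gender Female   2493  49.9
#> 2 gender Male     1956  39.1
#> 3 gender Unknown   551  11.0
```

`run_pipeline("config.yaml")` drives the same flow from a YAML file
(real quarterly files or a simulation block) and writes the screening
log, contingency tables, scored signal tables, descriptive summary,
formatted reports and run metadata as CSV/JSON; a thin CLI wrapper
lives at `inst/cli/faersignal`.

## Layout

* `R/` — I/O (`read_quarter`, `assemble_cases`, `read_meddra_map`),
  screening (`screen`, `deduplicate`, `match_target_drug`,
  `annotate_soc`), contingency (`build_pt_tables`, `build_soc_tables`),
  statistics (`ror_score`, `prr_score`, `chi2_score`, `bcpnn_score`,
  `ebgm_score`, `decide`, `score_all`), reporting (`describe`,
  `signal_report`, `run_pipeline`), synthetic data (`sim_config`,
  `generate_reports`, `truth_tables`)
* `vignettes/signal-mining-methods.Rmd` — models, assumptions,
  screening and counting conventions, generator design, limitations
* `tests/testthat/` — unit, property and acceptance suites
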