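---
title: "Disproportionality signal mining for spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal mining for spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(faersignal)
```

## The problem

Spontaneous-reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect suspected drug–adverse-event reports without a
denominator: there is no exposure population, only reports. Signal
detection therefore works by *disproportionality*: for a target drug
and a candidate event, one asks whether the event is reported more
often with the drug than the rest of the database would predict. The
unit of analysis is the 2×2 "four-grid" for one drug–event pair:

|              | target event | other events |
|--------------|--------------|--------------|
| target drug  | a            | b            |
| other drugs  | c            | d            |

with `N = a + b + c + d`. faersignal builds this pipeline end to end
for a FAERS-style corpus: ingest of the quarterly `$`-delimited
DEMO/DRUG/REAC/OUTC tables, screening and deduplication, restriction
to reports naming the target drug as primary suspect (the motivating
use case is capmatinib, a selective MET inhibitor for
*MET* exon-14-skipping NSCLC, searched under "Tabrecta" and
"Capmatinib"), four-grid construction at MedDRA preferred-term (PT)
and system-organ-class (SOC) level, and scoring with four families of
disproportionality statistics.

## The statistics

All four statistics, and the Pearson chi-square reported alongside,
are deterministic functions of `(a, b, c, d)`:

* **ROR** `= ad/bc`, with the Woolf interval
  `exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`.
* **PRR** `= [a/(a+b)] / [c/(c+d)]`, with
  `SE(ln PRR) = √(1/a − 1/(a+b) + 1/c − 1/(c+d))`.
* **χ²**, with the Yates continuity correction by default (the
  convention in published FAERS tables; a flag disables it).
* **BCPNN IC**: the posterior expectation of
  `log2 p(x,y)/(p(x)p(y))` under independent Beta priors on the
  marginal reporting probabilities, with the canonical hyperparameters
  `α₁ = β₁ = γ₁₁ = 1`, `α = β = 2` and the joint prior parameter
  `γ = γ₁₁(N+α)(N+β)/((a+b+α₁)(a+c+β₁))`. The reported lower bound is
  `IC025 = E(IC) − 2·√V(IC)` with the Bate-style three-term variance —
  the "minus two standard deviations" convention, not a posterior
  quantile. The priors keep every table, however degenerate, finite.
* **EBGM**, implemented in its closed observed-over-expected form
  `aN/((a+b)(a+c))` with `EBGM05 = exp(ln EBGM − 1.96·√(1/a+1/b+1/c+1/d))`.
  This is *not* the full multi-item gamma-Poisson shrinker: no
  hyperparameters are estimated. The choice is recorded in every run's
  metadata file, because the two differ at small counts.

A pair is called a signal per algorithm by the conventional rules —
ROR and PRR require `a ≥ 3` and a 95% CI lower limit above 1, BCPNN
requires `IC025 > 0`, EBGM requires `EBGM05 > 2` — and a *consensus*
signal (`pass_all`) when all four fire. No multiple-testing adjustment
is applied; the thresholds are the only filter, as is standard in this
literature.

```{r}
score_all(tibble::tibble(event_id = "OEDEMA PERIPHERAL", level = "PT",
                         a = 10, b = 90, c = 100, d = 9900))[
  , c("event_id", "ror", "ror_low", "prr", "chi2", "ic", "ic025",
      "ebgm", "ebgm05", "pass_all")]
```

## Screening choices

Several published screening steps are ambiguous at the report level;
the package fixes them as follows and logs every removal by reason so
the choices are auditable:

* **Deduplication.** FAERS re-submits updated versions of a case; for
  each `caseid` exactly the highest `caseversion` is kept, ties broken
  by latest FDA receipt date, then largest `primaryid`. The rule is
  deterministic, so deduplication is idempotent and order-independent.
* **Missing patient information.** A report is dropped only when sex,
  age, country *and* reporter are all missing. Published descriptive
  tables keep large "Unknown" strata (70.92% unknown age), so any
  single missing field cannot have been exclusionary.
* **Minimum count.** The "more than three records" selection is
  realized as the `a ≥ 3` gate of the ROR/PRR thresholds — a
  drug–event pair with fewer than three target reports is never called
  a signal — not as a per-case record filter, which would contradict
  the published report counts.
* **Drug matching** is case-insensitive substring matching on both the
  verbatim drug name and the active-ingredient field, because FAERS
  free-text names carry dose and formulation suffixes.

## Counting unit

Published SOC-level counts can exceed the number of reports (one SOC
carries n = 1793 against 1991 total reports), which is only arithmetically
possible if each (report, PT) occurrence counts, not each report. The
default `counting_policy("pair")` therefore counts occurrences: `a` is
the number of (report, PT) occurrences of the event in target reports,
and the margins `a+b` (all target occurrences) and `c+d` (all
background occurrences) are shared by every table of a run. At SOC
level each occurrence is mapped to its SOC first, so two PTs of one
report in the same SOC contribute twice. `counting_policy("report")`
is available for the per-report convention. The unit is recorded in
the run metadata. MedDRA itself is licensed content, so the PT→SOC map
is always supplied by the user (columns `pt`, `soc_name`, `soc_code`);
unmapped PTs are tagged `UNMAPPED`, excluded from SOC tables, and
counted.

## Numerical choices

* Zero cells: scores that would be undefined raise an error naming the
  cell, or apply the Haldane–Anscombe 0.5 correction to all four cells
  of the affected table when `correction = "haldane"` (the pipeline
  default; raw cells are always reported alongside). For EBGM the
  point estimate always uses raw cells and only the interval is
  corrected.
* Cells are coerced to doubles before products such as
  `(a+b)(c+d)(a+c)(b+d)`, which overflow 32-bit integers.
* Ranking is deterministic: EBGM descending, ties broken
  lexicographically by event id. Percentages round half-up to two
  decimals, the convention that reproduces published values at
  boundaries.
* The Yates reduction `|ad−bc| − N/2` is floored at zero, matching
  `stats::chisq.test`.

## The synthetic generator

`sim_config()`/`generate_reports()` emulate the *structure* of a FAERS
extract with known truth, so every stage is testable offline: per-case
drug records with role codes (`PS`/`SS`/`C`/`I`), multiple reaction
PTs per case, case versioning (a `duplicate_rate` fraction of cases is
re-emitted as a superseding version), field-level missingness, and
demographic strata whose default probabilities mirror the published
capmatinib report profile (female 0.4937, consumer 0.5359, United
States 0.6253, unknown age 0.7092, death 0.2602, and so on). Arm sizes
default to 20,000 target and 20,000 background reports.

Signals are planted multiplicatively: an exposed report draws a
planted PT with probability `min(1, background_prob × RR)`. This makes
the planted RR the natural estimand of the rate-ratio statistics. Each
report draws every catalog PT independently (default: 100 PTs at
probability 0.02, so the per-report PT count is Poisson-binomial with
mean 2; at least one PT is enforced). All randomness derives from the
config seed; the same config is byte-identical on disk.

What the generator does *not* emulate: drug co-reporting networks,
confounding between demographics and events (a hook exists in the
design but defaults to independence), reporting trends over time, and
free-text term noise. Passing recovery tests on synthetic data
therefore demonstrate the pipeline's correctness as software and the
estimators' behaviour under the stated sampling model — not robustness
to the biases of real spontaneous-report data.

### A caution on EBGM and corpus composition

With a single planted pair, the ROR recovers the planted RR exactly in
expectation, because `ad/bc` cancels the shared margins. The
observed-over-expected EBGM does not when the target drug is a large
share of the corpus: its expected count `(a+b)(a+c)/N` is itself
inflated by the signal. At the default half-and-half composition a
planted RR of 10 yields an expected EBGM of only ≈ 1.7; the bias
disappears as the target share shrinks toward the real-FAERS regime
(a target drug is a tiny fraction of the database), which the test
suite demonstrates by contrast. This is a property of the estimand,
not an implementation artifact, and it is why EBGM-based recovery
fails under an equal-arm simulation design while ROR/PRR-based
recovery succeeds.

## Problem sizes used in the checks

The bundled checks run the formula suite on 1,000 random tables
against an independent brute-force evaluation (agreement to 10⁻⁹
relative error), full-size synthetic studies of 20,000 + 20,000
reports for recovery and null calibration, 100 seeded replicates for
the recovery rates, and smaller corpora (hundreds of reports) for
structural round-trip and screening tests.

## Limitations

The package deliberately stops where the published methodology stops:
no stratified or regression-adjusted disproportionality, no
time-to-onset analysis, no full MGPS fit, no probabilistic record
linkage beyond case-version deduplication, and no bundled MedDRA
content. Signals are disproportionate-reporting findings, not causal
claims.
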