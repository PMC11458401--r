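Package: faersignal
Title: Disproportionality Signal Mining for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection from
    FAERS-style spontaneous adverse-event report tables. Reads quarterly
    '$'-delimited DEMO/DRUG/REAC/OUTC files, screens and deduplicates case
    reports, restricts to a target drug as primary suspect, builds 2x2
    contingency tables for every drug-event pair at MedDRA preferred-term
    and system-organ-class level, and computes four disproportionality
    statistics with their intervals: the reporting odds ratio (ROR), the
    proportional reporting ratio (PRR), the Bayesian confidence propagation
    neural network information component (IC with IC025), and the empirical
    Bayes geometric mean in its observed-over-expected form (EBGM with
    EBGM05). Signals are called against the conventional thresholds and
    ranked by EBGM. A synthetic spontaneous-report generator with planted
    relative risks, duplicate case versions, missingness and demographic
    strata makes every pipeline stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    stringr,
    rlang,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
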