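Package: faersror
Title: Disproportionality Signal Detection and Prioritization for FAERS
    Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pharmacovigilance pipeline for the FDA Adverse Event
    Reporting System (FAERS) Quarterly Data Extract files: ingestion of the
    "$"-delimited ASCII tables (DEMO, DRUG, REAC, OUTC, THER, INDI plus
    deleted-case lists), caseid/primaryid deduplication, case/non-case
    reporting odds ratio (ROR) signal detection at MedDRA preferred-term and
    system-organ-class level, serious versus nonserious comparison with
    automatic chi-squared/Fisher test selection, five-feature semiquantitative
    clinical-priority scoring of signals, Weibull shape-parameter
    time-to-onset analysis, subgroup and sensitivity analyses, and a synthetic
    FAERS generator with planted ground truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    fitdistrplus,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
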