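Package: faersror
Title: Disproportionality Analysis of FAERS Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection from FDA Adverse
    Event Reporting System (FAERS) quarterly ASCII releases. Reads the
    DEMO/DRUG/REAC file trio, applies standard cleaning rules (health
    professional reporter filter, latest-case-version deduplication,
    primary-suspect ingredient extraction, missing-essential exclusion),
    and computes reporting odds ratios (ROR) with Wald confidence
    intervals, including sex- and age-subgroup comparisons via a z test on
    log RORs. Ships a synthetic FAERS quarter generator with injectable
    drug-event association strengths for end-to-end validation, pie and
    forest plot renderers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
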