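Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection from spontaneous
    adverse-event report databases in the style of FAERS extracts. Reads,
    deduplicates and filters report-level tables, builds 2x2 drug-event
    contingency tables, computes reporting odds ratios (ROR) and proportional
    reporting ratios (PRR) with Wald confidence intervals and chi-square
    statistics, applies joint ROR/PRR screening criteria, ranks signals,
    aggregates them over MedDRA-style preferred-term to system-organ-class
    mappings, and summarises reporter demographics. Includes a synthetic
    report generator with planted drug-event associations of known odds
    ratio for calibration and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
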