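Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance toolkit for FAERS-style spontaneous reporting
    data. Parses quarterly ASCII extracts (DEMO, DRUG, REAC, THER, INDI, OUTC),
    deduplicates case versions, identifies reports for a target drug by name
    and role code, and screens adverse-event preferred terms with four
    disproportionality algorithms (reporting odds ratio, proportional
    reporting ratio with chi-squared, the BCPNN information component, and an
    observed-to-expected ratio with EBGM-style bounds). Also provides
    time-to-onset summaries with Weibull shape-parameter classification,
    subgroup and sex-stratified analyses with FDR-adjusted volcano
    coordinates, and a synthetic FAERS-like data generator with planted
    drug-event associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    fitdistrplus,
    withr
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
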