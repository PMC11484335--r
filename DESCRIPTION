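Package: ariphen
Title: Acute Respiratory Infection Phenotyping and Sentinel Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rule-based electronic health record phenotyping of
    acute respiratory infection (ARI) in primary-care sentinel surveillance
    networks. Implements a core subset of the SNOMED CT Expression Constraint
    Language (ECL) evaluated against a polyhierarchical clinical terminology,
    a three-level ARI indicator hierarchy resolved to dynamic codelists,
    hierarchical case detection from coded event streams with 28-day episode
    deduplication, codelist validation by set analysis and code-frequency
    coverage, and stratified ISO-week incidence rates per 100,000 with
    denominator-quality filtering. A seeded synthetic-data module generates
    terminologies, practice registers and seasonal coded event streams with
    known ground truth so the full pipeline can be exercised and validated
    without access to real patient records.
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
    jsonlite,
    lubridate,
    igraph,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
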