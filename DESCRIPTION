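Package: taxcap
Title: Assessing Taxonomic Capacity Against Biodiversity Policy Demand
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, reproducible pipeline for quantifying the supply of
    taxonomic expertise from bibliographic metadata and relating it to the
    demand expressed by biodiversity policy. Builds a corpus of taxonomic
    articles from journal and article records, extracts scientific species
    names against a Darwin Core style taxonomic backbone, disambiguates
    authors with rule-based record linkage, aggregates policy species lists
    into an order-by-policy demand matrix, and fits a robust (Huber M)
    log-log regression of author counts on species richness and policy
    counts with residual diagnostics. Ships a synthetic bibliographic data
    generator with known ground truth so every stage is testable without
    network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    lmtest,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
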