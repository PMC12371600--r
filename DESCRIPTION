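Package: mdslisten
Title: Social Media Listening Pipeline for Myelodysplastic Syndrome Patient Forums
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable, fully tested pipeline for mining patient and
    caregiver experiences from myelodysplastic syndrome (MDS) forum
    corpora: corpus loading and cleaning (deduplication, UTF-8
    validation, spell autocorrection, exclusion filters), rule-based
    de-identification (name and manufacturer substitution, brand to
    International Nonproprietary Name normalization, username
    tokenization, clinical-trial post exclusion), patient-versus-caregiver
    role classification with an 80 percent majority rule and
    chronological fallback, high-risk MDS cohort extraction from
    treatment surrogate markers and blast-percentage parsing, theme
    hierarchy assignment with latent topic discovery, multilabel emotion
    classification with cohort-stratified prevalence tables, engagement
    and superuser analysis, thematic saturation curves, and a
    pre/post-COVID temporal split. Includes a seedable synthetic
    forum-corpus generator with exact ground-truth labels so every stage
    is testable without any scraped data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
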