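Package: soundmeaning
Title: Cross-Linguistic Form-Meaning Regularity from Sound-Class Phonetic Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether the meanings of foreign words can be
    inferred from their phonological form. Tokenizes IPA transcriptions, maps
    phones to coarse sound classes, computes normalized pairwise phonetic
    distances by global alignment, builds per-antonym-pair form-meaning
    regularity scores contrasting same- versus opposite-meaning translations
    across languages, and models trial-level forced-choice accuracy with
    binomial mixed-effects models (working-memory exclusions, sum coding,
    Sidak/Tukey follow-ups, simple slopes). A synthetic-data generator with a
    tunable iconicity parameter simulates lexicons, participants and responses
    so every stage is testable at desk scale, including permutation nulls and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    rlang,
    sandwich,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
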