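Package: vivomine
Title: Rule-Based Text Mining of Experimental Parameters and Risk-of-Bias
    Items from In Vivo Publications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts experimental parameters (species, sex, disease model,
    outcome modalities) and risk-of-bias items (randomization, blinding,
    animal-welfare compliance, conflict of interest, sample-size calculation,
    ARRIVE adherence, data availability) from full texts of preclinical in
    vivo publications using curated regular-expression libraries with
    IMRaD section scoping, together with an evaluation framework
    (sensitivity, specificity, precision, accuracy, F1, reporting
    prevalence, interrater agreement) and a synthetic-publication generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
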