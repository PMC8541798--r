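Package: prevcascade
Title: Similarity-Based Imputation and Projection of Country-Level Prevalence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates global counts of e-cigarette users ("vapers") from
    incomplete country-level survey data. Implements the average-similarity
    method: subgroup mean prevalences over WHO region, World Bank income
    group and legal-status strata are filled into unsurveyed countries
    through an ordered fallback cascade with provenance tracking and a
    simplified confidence ("goodness-of-fit") interval, prevalences are
    scaled to user counts by adult population, and the global total is
    projected to other years with a market-revenue index calibrated to a
    base year. A synthetic-world generator with hidden ground truth supports
    recovery experiments and full-pipeline testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
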