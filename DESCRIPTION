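Package: colipidr
Title: Phospholipidome Profiling and Marker Discovery for Solvent-Stressed
    Escherichia coli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for species-level bacterial phospholipidomics from
    HILIC LC-MS feature tables: in-silico glycerophospholipid database
    construction with exact deprotonated masses and 13C isotope envelopes,
    feature annotation with de-isotoping, forced integration and
    percent-of-total normalization, membrane acyl-property metrics
    (chain length, unsaturation, cyclopropane content), lipid-lipid
    correlation clustering, random-forest marker selection with backward
    elimination, Bayes-regularized ANOVA across lipidomes, and microplate
    growth-curve phenotyping (maximum specific growth rate, steady-state
    OD600, quality control). A fully seeded synthetic-study generator
    emulates a 116-construct knock-out/overexpression screen with and
    without 0.5% n-butanol so every pipeline stage can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
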