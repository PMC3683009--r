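Package: rdcascade
Title: Exome-Based Molecular Diagnosis of Recessive Retinal Dystrophies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable re-implementation of an exome-based molecular
    diagnosis workflow for recessive retinal dystrophies (RD). Provides a
    five-step variant filtering cascade (coding/non-silent consequence filter,
    160-gene RD panel restriction, allele-frequency filter against a
    dbSNP-style catalog, recessive/X-linked candidate-gene model, and
    known/novel mutation annotation), an exact Mendelian cosegregation
    probability computed by enumeration of transmission vectors, and a seeded
    synthetic exome cohort generator that emulates a 12-family study design so
    the whole pipeline is testable without any sequence download. Tibble-first
    interfaces throughout, with broom-style tidy() and glance() methods and
    ggplot2 visualisations.
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
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
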