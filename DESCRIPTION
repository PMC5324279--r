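Package: neovax
Title: Tumor Mutanome Uniqueness and Shared Neoantigen Set Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Cohort-scale analysis of tumor mutanome uniqueness and the
    population applicability of semi-universal poly-neoantigen vaccine sets.
    Provides a seeded synthetic-cohort generator with hotspot drivers and
    HLA subtype assignment, three-level alteration identity keys and
    uniqueness metrics, greedy cumulative "and" co-occurrence chains and
    additive "and/or" maximum-coverage selection, an MHC-I/II neoantigen
    calling pipeline with wild-type peptide subtraction behind a pluggable
    predictor contract (a deterministic surrogate predictor is included),
    and HLA-subtype population-frequency applicability arithmetic.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
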