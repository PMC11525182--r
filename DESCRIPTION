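Package: rvatnet
Title: Rare-Variant Gene Impairment Scoring with Set Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trait-agnostic gene impairment scoring for rare-variant
    association testing. A permutation-invariant set network aggregates
    per-variant annotations into a per-individual, per-gene impairment
    score, trained end-to-end against multiple quantitative traits using
    seed genes discovered by burden and SKAT score tests. Includes
    leakage-free cross-validated ensembling, gene-based association
    testing with expected-allele-frequency filtering and conditional
    analysis, pseudodosage export for single-marker testing frameworks,
    rare-variant-augmented phenotype prediction, and a synthetic-cohort
    generator with known ground-truth impairment for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
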