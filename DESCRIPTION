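Package: bcrtools
Title: B-Cell Receptor Repertoire Measures and Exposure Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted immunoglobulin heavy-chain (IGH)
    repertoire sequencing in epidemiological cohorts. Reads AIRR-standard
    rearrangement tables, infers B-cell clones by V/J partitioning and
    junction-distance clustering, collapses sequences into clone-isotype
    units, and computes per-participant repertoire measures: isotype usage
    and expression, somatic-hypermutation-gated class switching, V-allele
    usage, per-isotype CDR3 length, and Hill-number diversity profiles.
    Retained measures (by a cohort-level prevalence filter) are associated
    with smoking and vaping exposure groups through multivariable linear
    models with Benjamini-Hochberg false-discovery-rate tiers, including
    socioeconomic sensitivity and race-by-exposure interaction families.
    A seeded synthetic cohort generator produces AIRR files and metadata
    with configurable group effects for testing and power exploration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
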