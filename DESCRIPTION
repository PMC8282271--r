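Package: centiskat
Title: Rare-Variant Association Pipeline for Centenarian Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage rare-variant association pipeline for case-control
    studies of exceptional longevity. Implements gene-based kernel association
    tests (SKAT, SKAT-O, SKAT-C) from the quadratic-form score-test
    construction, including a pooled-sequencing adaptation that substitutes
    per-pool allele frequencies for individual genotypes; single-variant
    allelic and genotypic Fisher exact tests with LD reporting;
    functional-variant prioritization from regulatory and coding annotations;
    sub-pathway over-representation analysis; and seed-based shortest-path
    subnetwork extraction from protein-protein interaction networks. Ships a
    synthetic-cohort generator emulating the rare-heavy allele-frequency
    spectrum and genomic-region mix of targeted capture sequencing so the whole
    pipeline is testable without access data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
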