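Package: alloscreen
Title: Screening Metabolite-Transcription Factor Interactions from
    Paired Time-Course Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcription-factor (TF) activity profiles from
    time-course transcriptomics by topology-constrained network component
    analysis (NCA), screens all metabolite-TF pairs for Hill-type kinetic
    relationships between measured metabolite concentrations and inferred
    activities, and prunes candidate allosteric interactions with a
    metabolic-network distance criterion derived from a genome-scale
    stoichiometric model. Ships a synthetic-data generator with planted
    ground truth so every stage of the pipeline can be validated by
    recovery tests without external data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
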