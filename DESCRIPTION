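Package: otxtools
Title: Bait-Control Interactome Triage and Knockdown Transcriptomics for
    Choroid Plexus Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-omic studies of transcription-factor
    knockdown in the choroid plexus. Classifies putative protein partners from
    bait versus IgG co-immunoprecipitation peptide counts and builds
    cross-replicate and cross-structure consensus sets; computes signed fold
    changes, percent knockdown, and direction-consistent consensus gene lists
    across several knockdown comparisons; performs hypergeometric
    over-representation analysis with Benjamini-Hochberg correction; quantifies
    isoform usage fractions and flags isoform switches from transcript-level
    counts; and applies the 2^-ddCt method to qPCR cycle thresholds. Seeded
    synthetic-data generators with planted ground truth support
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr
Suggests:
    Biostrings,
    jsonlite,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
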