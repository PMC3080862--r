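Package: epitriad
Title: Integrative Chromatin, DNA Methylation, and Expression Analysis for
    Tag-Count Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for characterizing epigenomic
    differences between two cell populations from tag-count sequencing
    assays. Implements spatial-clustering (SICER-style) calling of
    ChIP-seq enriched islands against a matched input library, detection
    of broad repressive H3K27me3 domains ("blocs") above a span
    threshold, per-gene four-state chromatin classification (bivalent,
    K4-only, K27-only, neither) across cell types with the full
    64-pattern transition table, SAGE-seq tag-count normalization and
    four-class differential-expression calling, exact conditional
    testing of differentially methylated restriction sites from
    methylation-sensitive digital karyotyping (MSDK-seq) counts, and
    Fisher's-exact enrichment of joint methylation x chromatin x
    expression patterns. Ships a seeded synthetic-data generator that
    plants every kind of ground-truth feature on a toy genome so the
    whole pipeline is verifiable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
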