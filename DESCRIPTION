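Package: chiprx
Title: Spike-In Normalized Analysis of Global Chromatin and Transcriptional
    Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of ChIP-seq and RNA-seq experiments that
    use exogenous spike-in controls (ChIP-Rx with Drosophila chromatin;
    ERCC RNA spike-ins) so that genuine genome-wide shifts in signal are
    preserved rather than normalized away.  Provides read classification
    and exogenous-genome scaling factors, gene-body quantification and
    ordered-rank fold-change tables, scaled metagene profiles,
    ERCC-scaled differential expression, reproducible-peak and
    transcription-factor binding-site calling with nearest-TSS target
    assignment, expression-matched background gene sampling, figure-level
    statistics (Pearson fold-change correlations, multi-factor ANOVA), and
    a fully synthetic study generator emulating a hypoxia histone
    trimethylation experiment with wild-type and HIF-1beta knockout
    genotypes, for end-to-end testing without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    yaml,
    car,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
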