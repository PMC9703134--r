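Package: methdrift
Title: Passage-Associated DNA Methylation Drift in Organoid Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for culture-duration (passage) associated DNA
    methylation drift in intestinal organoid methylation-array data. Classifies
    CpGs into heteroskedastic, hypomethylated and hypermethylated drift classes
    from per-CpG linear models and Breusch-Pagan tests, decomposes methylation
    variance against sample phenotypes by PCA, and tests drift classes for
    enrichment in genomic features using feasibility-corrected resampling
    backgrounds and a replication-origin distance permutation test. Includes a
    synthetic-cohort generator that emulates bimodal array beta distributions,
    donor random effects and planted drift archetypes so the whole pipeline is
    testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr,
    yaml
Suggests:
    lmtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
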