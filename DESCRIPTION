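Package: capdesign
Title: Target Capture Design Construction and Coverage Performance Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds merged, padded hybrid-capture target designs from
    annotation interval tracks, evaluates per-region and per-base sequencing
    coverage at a depth threshold across multiple samples, classifies target
    regions into three performance groups with GC-content and bait-exclusion
    risk criteria, projects performance onto subset designs, partitions
    multiple designs into exhaustive membership classes, and aggregates
    per-sample sequencing statistics into study-level summaries. Includes a
    deterministic synthetic-data generator (toy genome, annotation and
    exclusion tracks, GC-dependent negative-binomial depth tracks, read sets)
    so the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
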