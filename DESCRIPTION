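Package: crossclock
Title: Cross-Species Transcriptome Aging Clocks from Multi-Study Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates transcriptome aging clocks that are conserved
    between two species (e.g. human prefrontal cortex and Drosophila head)
    from multi-study RNA-seq count matrices. Provides expression filtering,
    TMM and RLE library normalization with log-CPM transformation, Pearson
    correlation ranking of genes against chronological age, greedy best-match
    resolution of scored ortholog tables, cross-species intersection of
    top-ranked gene lists, and a resampled 75/25 train/test harness for age
    regression and three-group age classification with gradient-boosted tree
    models. A negative-binomial multi-study simulator with planted
    age-associated ortholog pairs supplies ground-truthed data so the whole
    pipeline can be exercised and verified without downloads.
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
    xgboost
Suggests:
    MASS,
    e1071,
    edgeR,
    jsonlite,
    optparse,
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
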