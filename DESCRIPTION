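Package: mirank
Title: Cross-Study Rank Aggregation of Predominant Food miRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analysis toolkit for microRNA abundance rankings reported
    across independent profiling studies of animal-source foods. Harmonizes
    heterogeneous mature-miRNA nomenclature (species prefixes, arm suffixes),
    aggregates per-study top-N lists into consensus rankings with a
    Borda-type frequency-weighted ordinal recurrence score, partitions the
    resulting presence structure into shared, product-selective and
    food-group-exclusive miRNAs (including persistence through processing),
    and provides generic target-coverage, hypergeometric over-representation
    and interaction-network analytics together with a seeded synthetic-data
    generator for rank-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
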