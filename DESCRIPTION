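Package: footprintr
Title: Hydroxyl Radical Footprinting Analysis and Cooperative Binding Fits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of high-throughput hydroxyl radical
    footprinting experiments on structured RNAs. Converts two-channel
    per-nucleotide cleavage intensities into normalized reactivities
    (reference set defined as the 8% most reactive nucleotides after
    excluding the top 2%), calls protein-induced protections and
    enhancements from bound-minus-free difference profiles, annotates
    GNRA tetraloop-receptor motifs on RNA secondary structures, and fits
    cooperative Hill binding models to filter-partitioning data. Includes
    a seeded synthetic-data generator that emulates capillary
    electrophoresis cleavage profiles, electropherogram peak trains, and
    binding curves, so the full pipeline is testable end to end.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
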