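Package: ppiscreen
Title: Post-Processing and Enrichment Analysis for Membrane Yeast
    Two-Hybrid Interaction Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns raw bait-prey hit tables from membrane yeast two-hybrid
    (MYTH) screens into annotated, statistically scored interactomes.
    Provides interaction deduplication, contaminant-prey filtering (signal
    peptide processing and ribosomal preys), known-interaction flagging,
    membrane-localization annotation, exact hypergeometric term enrichment
    with Benjamini-Hochberg correction over configurable backgrounds,
    drug-target and therapeutic-category enrichment, a two-step domain
    co-occurrence-set pair enrichment for interacting bait-prey pairs, a
    seeded synthetic screen generator with planted signals for end-to-end
    benchmarking, and orthogonal-validation rate summaries. All user-facing
    functions take and return tibbles so analyses compose with the pipe.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
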