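Package: mycomix
Title: Stable-Isotope Mixing Models and Mycobiont Community Summaries for
    Partially Mycoheterotrophic Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the fungal-derived carbon fraction of green plants
    suspected of partial mycoheterotrophy from leaf and rhizome stable-isotope
    data. Computes plot-normalized 13C and 15N enrichment factors against
    co-occurring autotrophic reference plants, calibrates a linear two-source
    mixing model with a full-mycoheterotroph (albino or protocorm) baseline,
    and compares groups with linear mixed models (random plot effect) and
    Tukey-Kramer post-hoc contrasts. Companion tools summarize mycorrhizal
    metabarcoding results: OTU-table filtering (singleton removal, trophic
    guild whitelists), relative abundance and dominance summaries, and a
    deterministic abundance-ranked greedy clusterer at 97 percent identity.
    Includes a synthetic-data generator that emulates the plot-based field
    design so every pipeline stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    multcomp,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
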