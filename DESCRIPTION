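Package: cooccurj
Title: Presence/Absence Co-Occurrence Analysis with Prevalence-Specific
    Null Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pairwise co-occurrence analysis of microbial presence/absence
    data. Computes Jaccard's index and the phi coefficient for every taxon
    pair of a taxon-by-sample table, and tests Jaccard's index against a
    prevalence-specific hypergeometric null distribution (the exact null of
    Veech's probabilistic model of species co-occurrence) instead of the
    flawed standard binomial null that assumes 50% prevalence for all taxa.
    Includes read-count thresholding to presence/absence, familywise-
    corrected all-pairs screening, concordance and prevalence-stratified
    diagnostics comparing the two metrics, seeded Monte-Carlo null
    distributions, and synthetic-community generators with known ground
    truth for calibration and power studies.
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
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
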