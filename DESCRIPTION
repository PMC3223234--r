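Package: synergynet
Title: Gene-Cooperation Networks from Information Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs phenotype-specific gene-cooperation networks from
    log2 expression data using pairwise information synergy: the gain in
    mutual information about a binary phenotype contributed by the joint
    expression of a gene pair over the sum of the genes' individual
    contributions. Provides metabolite-trend-based gene selection,
    discretization-based mutual information estimation, permutation testing
    with Benjamini-Hochberg false-discovery-rate control, network assembly
    and topology diagnostics, hypergeometric pathway enrichment and
    pathway-neighbor association ranking, a differential-correlation
    baseline network, and a synthetic-data generator with planted
    cooperative gene pairs for calibration and benchmarking.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
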