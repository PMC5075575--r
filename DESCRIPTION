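Package: magicqtl
Title: Haplotype-Based QTL Mapping for Multi-Parent (MAGIC) Wheat Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for eight-founder MAGIC
    (multi-parent advanced generation inter-cross) recombinant inbred line
    populations. Provides a funnel-crossing population simulator with known
    founder mosaics and planted QTL, founder-descent probability
    reconstruction by a forward-backward hidden Markov model, haplotype
    dosage regression genome scans (additive and full diplotype models),
    permutation-based genome-wide significance with Storey q-value FDR,
    forward-selection conditional (composite) scans, and the phenotype
    preparation stages used in phenology studies: derived developmental
    intervals, chained-equation imputation, trait correlation and PCA, and
    kinship-matrix population-structure checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
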