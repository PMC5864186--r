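Package: ecosig
Title: Phage Ecogenomic Signatures for Microbial Source Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Profiles the relative abundance (hits per megabase) of
    phage-encoded open reading frames across metagenomes from homology-search
    hit tables, and uses the resulting habitat-specific "ecogenomic
    signatures" for virome-based microbial source tracking. Provides
    square-root transformation, Bray-Curtis dissimilarity, non-metric
    multidimensional scaling and ANOSIM implemented from their definitions;
    in silico simulation of faecal pollution of environmental viromes,
    including Monte-Carlo permutation of environmental backgrounds;
    ROC-based threshold selection and a two-step classifier that detects
    pollution and attributes it to a human source; Kruskal-Wallis/Dunn
    habitat-affiliation statistics for individual ORFs; and a synthetic
    cohort generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    Biostrings
Config/testthat/edition: 3
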