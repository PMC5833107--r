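Package: taxafun
Title: Taxa-Function Robustness of Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how robust a microbial community's aggregate
    functional profile is to perturbations of its taxonomic composition.
    Simulates stochastic multiplicative perturbations of OTU relative
    abundances, maps taxonomic to functional profiles through a linear
    genome-content model with 16S copy-number normalization and pathway
    summarization, measures perturbation magnitude with weighted UniFrac and
    functional shift with cosine dissimilarity, and fits a power-law
    taxa-function response curve yielding two robustness factors
    (attenuation and buffering). Also computes five gene-distribution
    features describing how functions are apportioned across community
    members' genomes, and estimates robustness from paired real communities
    by convex mixing of taxonomic and functional profiles with a binary
    search on the mixing fraction. Includes a synthetic-data generator with
    a tunable between-genome redundancy parameter so the full workflow can
    be exercised without external reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    vegan,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    phyloseq,
    biomformat,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
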