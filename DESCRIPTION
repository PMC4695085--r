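Package: symcomm
Title: Symbiodinium ITS2 Community Analysis Across Reef Habitat Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Symbiodinium ITS2 amplicon communities
    sampled from reef water, sediment, and coral tissue. Implements a
    hierarchical taxonomy assigner (clade-level e-value classification,
    subtype assignment by local alignment with lowest-common-ancestor
    placement of ambiguous hits, and greedy 97% de novo clustering of
    novel sequences), square-root transformed Bray-Curtis community
    analysis with NMDS ordination and permutational MANOVA, Bayesian
    Poisson-lognormal differential abundance testing with a sum-taxon
    sequencing-depth normalizer, Mantel tests of spatial autocorrelation
    on projected GPS coordinates, and a truth-known synthetic data
    generator covering reference databases, communities, and reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    ape,
    phangorn,
    vegan,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
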