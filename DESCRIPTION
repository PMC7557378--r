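Package: fecology
Title: Diversity, Differentiation and Co-Occurrence Analysis of Fungal
    Endophyte Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of amplicon-derived fungal
    endophyte community (FEC) profiles sampled from multiple host species
    across multiple sites. Covers dataset bookkeeping (species-level
    agglomeration, read-depth and rarity filters, shared-taxon partitions),
    incidence-based Hill-number rarefaction and extrapolation with bootstrap
    intervals, assignment-based (Kosman) dispersion and differentiation
    statistics with permutation tests and effective-number normalisation,
    Bray-Curtis and Dice dissimilarities with principal coordinate ordination
    and PERMANOVA/ANOSIM group tests, and cross-site Spearman co-occurrence
    networks with hub-taxon identification. A synthetic multi-host,
    multi-site community generator with known ground truth supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vegan,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
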