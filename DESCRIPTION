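Package: specdelim
Title: Integrative Species Delimitation from Multi-Locus Distances, Trees,
    Haplotype Networks and Craniodental Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative species delimitation in small mammals and
    other non-model taxa. Computes Kimura two-parameter (K2P) distances (all
    substitutions or transversions only) with pairwise deletion, group-level
    divergence summaries, and rate-based divergence dating; tree-based
    delimitation statistics including reciprocal monophyly, Rosenberg's
    probability of monophyly under random coalescence, intra/inter distance
    ratios and leave-one-out probability of correct identification;
    statistical-parsimony-style haplotype networks; and a craniodental
    morphometric pipeline (missingness filters, correlation pruning,
    predictive-mean-matching imputation, correlation PCA, Mosimann log-shape
    ratios, UPGMA clustering and k-nearest-neighbour classification). A
    seeded synthetic-data module generates sequence alignments under a K2P
    substitution process and morphometric tables with group size factors, so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
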