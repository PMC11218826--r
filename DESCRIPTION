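Package: nlrmacro
Title: Desk-Scale Macroevolutionary Analysis of Plant NLR Immune Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying the macroevolution of plant NLR (nucleotide-binding,
    leucine-rich repeat) immune receptors at desk scale: domain-architecture
    classification of receptors into categories and subtypes with integrated-domain
    inventory, greedy identity/coverage sequence clustering of N-terminal domains,
    iterative long-branch cleaning of homolog trees (absolute and sister-relative
    cutoffs with column-occupancy filtering), thresholded structure-similarity
    networks with Louvain community detection and sequence-vs-structure
    cross-tabulation, profile-HMM scoring of N-terminal motifs (MAEPL/MADA style)
    in bits, and cross-species orthologous differential-expression concordance with
    Fisher/Benjamini-Hochberg enrichment. A seeded synthetic-data generator produces
    proteomes, trees, similarity matrices and expression tables with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
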