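Package: pdinet
Title: Gene-Centered Protein-DNA Interaction Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis framework for gene-centered protein-DNA interaction
    (PDI) networks of the kind produced by enhanced yeast one-hybrid screens:
    bipartite TF-to-promoter network construction and bait-quality filtering,
    degree statistics and PDI density matrices, degree-preserving edge-switch
    randomization nulls for overlap significance, energy-based position weight
    matrix scanning of proximal promoters, k-mer elementary-motif discovery
    from bound versus unbound promoters, activator/repressor inference from
    TF-target co-expression with shuffle nulls, cofactor-based regulatory-sign
    classification, TF-GO term association scanning with randomized-network
    nulls, and a TF association (redundancy) network with essentiality and
    family statistics. Includes a seeded synthetic-data generator with planted
    ground truth so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
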