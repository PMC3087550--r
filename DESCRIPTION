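Package: PoGOfam
Title: Ortholog Group Delineation and Founder-Gene Inference for Green
    Plant Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling a gene family across green plants from
    proteomes and translated expressed sequence tags (ESTs): local-alignment
    homology harvesting with coverage filtering and redundancy collapse,
    progressive multiple protein alignment, distance-based phylogenies
    (p-distance and PAM-001 correction, neighbor joining, nonparametric
    bootstrap, outgroup rooting), delineation of possible groups of
    orthologs (PoGOs) on support-annotated gene trees, founder-gene counts
    along the green-plant lineage ladder, Dollo-parsimony gain/loss
    inference, and a duplication/loss birth-death simulator that provides
    gene families with known orthology for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    ape,
    Biostrings,
    S4Vectors,
    phangorn,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
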