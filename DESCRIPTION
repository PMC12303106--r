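Package: cooccurModules
Title: Detection of Non-Neutral Species Modules from Co-Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect groups of species that deviate from neutral
    community assembly using presence-absence co-occurrence data collected
    along an ecological gradient. Implements a conservative, distribution-free
    pairwise test of species rank consistency, builds the resulting
    rank-consistency network, finds modules with the Leiden algorithm and
    extracts robust module cores over replicate runs, and interprets modules
    with cross-validated classification trees on species traits. Includes a
    spatially implicit environmental-filtering metacommunity simulator (with
    the Dirichlet-multinomial neutral model as a special case) and a factorial
    virtual-experiment harness for power and false-positive studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    rpart,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Network, Clustering, GraphAndNetwork, Classification
RoxygenNote: 7.3.3
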