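Package: gocensus
Title: Phylogenomic Trees and Evolutionary Timelines from a Genomic
    Census of Gene Ontology Molecular Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds genome-by-term abundance matrices of Gene Ontology
    molecular-function terms from annotation (GAF) files and an OBO
    ontology, encodes abundances as 32-state linearly ordered characters,
    reconstructs most-parsimonious trees of functions and of organisms
    under Wagner (additive) parsimony with stepwise addition and tree
    bisection-reconnection, roots them by the Lundberg method, and derives
    evolutionary timelines (node-distance ages), distribution indices,
    superkingdom Venn groups, fit indices (CI/RI/HI), genealogical sorting
    indices, age-binned functional tables, accumulation curves and the
    multi-level term network with hub detection. Includes a synthetic-data
    generator (DAG plus birth-spread-loss functionomes with optional
    horizontal transfer) providing ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
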