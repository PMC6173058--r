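Package: ESSim
Title: Essentiality Scoring of Reactions and Genes in Constraint-Based
    Metabolic Models
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the essentiality of every reaction and gene in a
    genome-scale metabolic model by enumerating minimal lethal knockout
    sets up to a user-chosen cardinality with flux balance analysis, and
    converting the enumeration into a normalized essentiality score that
    is comparable across models. Reads SBML Level 3 (fbc) and BiGG-style
    JSON models, evaluates gene-protein-reaction boolean rules, ships a
    pruned synthetic-lethality search together with an exhaustive
    brute-force oracle, derives metabolite-metabolite, reaction-reaction
    and gene-gene graphs for topology-centrality baselines, and compares
    score tables between models (e.g. wild-type versus knockout strains).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    xml2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
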