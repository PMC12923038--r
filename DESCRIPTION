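Package: enhrank
Title: Disease-Enhancer Prioritization by Random Walk with Restart on
    Multiplex-Heterogeneous Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a disease similarity network from ontology annotations
    (Resnik semantic similarity over the Disease Ontology DAG), a shared
    target-gene enhancer network (hypergeometric overlap tests) and a
    sequence-similarity enhancer network, integrates them into a
    multiplex-heterogeneous network, and ranks candidate enhancers for a
    query disease with an extended random walk with restart.  Includes
    per-disease k-fold cross-validation with AUC scoring, parameter sweeps,
    network ablations, readers and writers for the standard file formats
    involved (OBO, BED, FASTA, similarity matrices, TSV tables), and a
    synthetic fixture generator so the whole pipeline can be exercised
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    withr,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    pROC
Config/testthat/edition: 3
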