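Package: prkern
Title: Pairwise Rational Kernels for Supervised Metabolic Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts enzyme-enzyme interactions in metabolic networks
    directly from raw nucleotide sequences using pairwise rational kernels:
    pairwise similarity operators (direct sum, tensor product, metric
    learning, Cartesian) whose base kernel is an n-gram (spectrum) kernel
    realized by weighted finite-state transducer composition.  Provides a
    minimal weighted automaton/transducer algebra over the real semiring
    (inverse, composition with epsilon filtering, output projection, exact
    path sums on acyclic machines), n-gram counting transducers and Gram
    matrix construction, a metabolic-network data model with balanced
    negative sampling, a pairwise support vector machine on precomputed
    Gram matrices with cross-validated ROC-AUC evaluation and McNemar
    comparison of classifiers, and a seeded generator of planted-motif
    synthetic benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    kernlab,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
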