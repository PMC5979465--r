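Package: protstab
Title: Three-Class Protein Variant Stability Classification from Curated
    Thermodynamic Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and evaluating a sequence-based classifier
    of amino acid substitution effects on protein stability (increase,
    no effect, decrease in the free energy of unfolding). Implements
    curation of thermodynamic variant records with auditable rejection
    reasons, a 1106-feature descriptor combining experimental conditions,
    multiple-sequence-alignment conservation and co-evolution scores,
    AAindex physicochemical indices, substitution type encodings and
    sequence-neighbourhood composition, homology-aware cross-validation
    partitioning, two-step greedy feature selection (per-fold backward
    elimination followed by forward selection), a two-layer balanced
    random-forest cascade, and a full evaluation suite including the
    correct prediction ratio, generalized squared correlation and
    class-size normalization of confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    randomForest,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
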