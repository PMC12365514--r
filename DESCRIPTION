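Package: ptmnet
Title: PTM-Disease Association Scores and Score-Weighted Disease
    Subtype Classification with Graph Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts post-translational-modification (PTM) potentiality
    scores for protein-disease pairs from a heterogeneous network of known
    associations, Gaussian interaction profile kernels and local
    sequence-alignment similarity, using a layer-attention graph
    convolutional network with a bilinear decoder.  The decoded scores
    exponentially re-weight protein-expression features before transductive
    GCN disease-subtype classification, PTM-biomarker screening by
    cross-validation frequency, and shared-protein sensitivity analysis.
    Includes a synthetic-data generator with planted block structure for
    end-to-end testing, TSV/FASTA readers and writers, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
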