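Package: mdacomp
Title: miRNA-Disease Association Prediction by Truncated Schatten p-Norm
    Matrix Completion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations by completing a
    heterogeneous similarity/association matrix. Disease semantic similarity
    is computed from ontology DAGs (two contribution schemes, averaged),
    miRNA and disease Gaussian interaction-profile kernel similarities are
    derived from the binary association matrix, and the fused similarities
    frame the known associations in a block target matrix. Missing entries
    are recovered by minimising the truncated Schatten p-norm with a
    box-constrained ADMM whose low-rank step is a weighted singular-value
    contraction. Includes cross-validation protocols (global leave-one-out,
    k-fold), ranking and confusion metrics, a sparsity-sensitivity
    experiment, and a synthetic planted low-rank data generator so the full
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
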