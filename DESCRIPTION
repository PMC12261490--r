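Package: marlene
Title: Meta-Learned Temporal Gene Regulatory Networks from Time-Series Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed, cell-type-specific, time-varying transcription
    factor to target gene regulatory networks from time-series single-cell
    RNA-seq expression data. Each time point's cell population is summarised by
    a permutation-invariant pooling-by-multihead-attention set encoder; a
    self-attention layer whose query/key projection weights evolve across time
    points through matrix-valued gated recurrent units produces one
    row-stochastic gene-by-TF adjacency matrix per time point; gene expression
    is reconstructed from TF expression through the inferred adjacency and used
    to classify the batch's cell type. All parameters are trained with
    model-agnostic meta-learning, treating each cell type as a task so that
    networks can be recovered even for rare cell populations. Includes a
    planted-network single-cell count simulator, GRN sparsification and
    benchmarking utilities (Fisher overlap tests, Benjamini-Hochberg
    correction, edge-set intersection-over-union), and edge-recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
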