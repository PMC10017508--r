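Package: ncemr
Title: Node-Centric Expression Models for Spatial Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits node-centric expression models (NCEMs): regression and
    small neural models that predict a cell's gene expression from its
    cell type and the composition of its spatial niche on a
    radius-thresholded cell graph. Includes closed-form linear NCEMs with
    Wald tests for sender-receiver type couplings, a variant for
    deconvoluted spot transcriptomics, nonlinear and ligand-receptor
    graph-kernel models, a conditional variational autoencoder with style
    transfer, interpretation utilities (type coupling, sender/receiver
    effects, sender similarity, cluster enrichment), and simulators that
    generate spatially dependent expression data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
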