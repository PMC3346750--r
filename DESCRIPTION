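Package: sparsegrn
Title: Sparse Two-Layer Gaussian Graphical Models for Transcriptional
    Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers bipartite transcriptional regulatory networks from gene
    expression data with a sparse two-layer linear-Gaussian model: each gene's
    expression is a linear function of observed transcription-factor expression
    plus hidden Gaussian factors, fitted by L1-penalized maximum marginal
    likelihood using an orthant-wise limited-memory quasi-Newton (OWL-QN)
    optimizer. Includes out-of-sample log-likelihood cross-validation against
    a no-hidden-factor model and an independent-genes reference model,
    gene-set enrichment with Fisher's exact test and randomization
    calibration, a network component analysis (NCA) baseline with a frozen
    connectivity pattern, a synthetic-data generator matching the model's
    generative assumptions, and readers for TSV/GCT expression matrices, GMT
    gene-set collections, and plain-text transcription-factor lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
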