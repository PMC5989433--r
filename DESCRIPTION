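Package: pciNet
Title: Pathway Cross-Talk Inhibition Networks for Cancer Subtypes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds subtype-specific networks of cross-talking pathways from
    labelled gene expression data and simulates in silico drug-induced
    pathway inhibition. Differentially expressed genes are mapped onto
    pathway gene sets by Fisher's exact enrichment; pathway pairs are scored
    per sample with a discriminating score and ranked by cross-validated
    random-forest AUC inside Monte Carlo bootstraps; the resulting pathway
    network is probed by node deletion, quantifying the percentage of
    network efficiency abolished by inhibiting single pathways, pathway
    pairs, or the pathway sets targeted by a drug. Includes a synthetic data
    generator with planted differentially expressed pathways so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
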