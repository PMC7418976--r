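Package: txlate
Title: Cross-Domain Translation of Drug-Induced Gene Expression Time Series
Version: 0.1.0
Authors@R: person("txlate", "maintainers", email = "maintainers@txlate.dev",
    role = c("aut", "cre"))
Description: Tools for predicting a target domain's drug-induced gene
    expression trajectory (for example human hepatocytes in vitro, or rat
    liver in vivo) from a source domain's trajectory (rat hepatocytes in
    vitro) for a previously unseen compound.  Implements the level-plus-slope
    trajectory encoding, pairwise replicate matching into learning examples,
    leave-one-compound-out cross-validation, five translation models
    (a bottleneck feed-forward network, a modified autoencoder initialised by
    grafting pre-trained per-domain encoder and decoder halves, a gene-axis
    convolutional network, k-nearest neighbours and a multi-output random
    regression forest), paired-t/Benjamini-Hochberg model comparison, and a
    synthetic paired-cohort generator with a noise-free oracle for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
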