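Package: asgcn
Title: Adaptive Spatiotemporal Graph Convolutional Networks for Multichannel fNIRS Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of multichannel functional near-infrared spectroscopy
    (fNIRS) recordings with an adaptive spatiotemporal graph convolutional
    recurrent network. Channels are graph nodes; the adjacency matrix is learned
    from a low-rank node embedding (adaptive graph learning), per-node
    convolution weights are generated from a shared weight pool (node weight
    adaptive learning), and gated recurrent units whose gates are graph
    convolutions capture temporal structure. Includes a sliding-window data
    pipeline with subject-level stratified splits, a synthetic cohort generator
    with planted channel-coupling graphs, training with Adam and early stopping,
    binary classification metrics and ROC/AUC, experiment grids over window
    length, hemoglobin attribute and cortical region, and learned-connectivity
    reporting with edge-deletion ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
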