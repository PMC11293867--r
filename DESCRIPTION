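Package: dppa
Title: Determinantal Point Process Attention over Grid Cell Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying out-of-distribution generalization in
    relational tasks using a biologically inspired position code. Provides an
    analytic grid-cell encoder that maps 2D integer locations to
    frequency-by-phase firing-rate embeddings, a determinantal point process
    (DPP) attentional objective that selects the spatial frequency whose
    embeddings cover the training region with maximal variance and minimal
    redundancy, generators for multiple-choice analogy and arithmetic
    problems with translated and scaled test regions, LSTM and transformer
    candidate-scoring networks trained by backpropagation, and a two-phase
    training procedure together with baseline and ablation models for
    comparing generalization across increasingly remote test regions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
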