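Package: deltaHMM
Title: Feature Selection for Gene Expression Time Series with a Two-State
    Hidden Markov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects and ranks relevant genes from replicated gene-expression
    time courses. Expression profiles are rearranged per condition into
    feature x replicate x time arrays, reduced to consecutive-time
    differences to remove per-gene offsets, and modelled with a two-state
    (change / no-change) hidden Markov model with multivariate Gaussian
    emissions over replicates. Parameters are estimated by
    expectation-maximization over all features pooled as independent
    observation sequences; each feature's state path is decoded per
    condition with the Viterbi algorithm. Features whose control path is
    flat while at least one treated condition changes are selected, then
    ranked by number of decoded changes, total magnitude of change, and
    replicate consistency. Includes a ground-truth simulator for
    two-condition time-course designs and detection-performance evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
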