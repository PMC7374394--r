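Package: hscnn
Title: Harmony Search Hyperparameter Optimization for 1D CNN Respiration
    Pattern Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete Harmony Search (HS) metaheuristic for optimizing the
    per-layer kernel sizes, kernel counts and dense-layer widths of a
    one-dimensional convolutional neural network that classifies five
    respiration patterns (eupnea, bradypnea, tachypnea, apnea, movement)
    from fixed-length chest-motion signal pieces.  Includes the discrete
    search-space algebra with exact cardinality arithmetic, the HS engine
    with memory recall, pitch adjustment, replace-worst updates and a
    stagnation-based early stop, a from-scratch trainable 1D CNN objective,
    a synthetic respiration-signal generator emulating an ultra-wideband
    radar acquisition protocol, and a pipeline layer with a command-line
    interface, grid-search and random-search baselines and a cheap
    surrogate objective for optimizer verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    nnet
Config/testthat/edition: 3
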