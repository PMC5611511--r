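Package: fpspace
Title: Supervised Classification Spaces for Fixed-Point Network Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs low-dimensional classification state spaces from
    multi-node timeseries recordings of fixed-point (attractor) networks,
    such as insect antennal-lobe projection-neuron populations. Implements
    exclusive threshold reduction (ETR) and its convexly re-weighted variant
    (OETR) on libraries of dominant per-stimulus SVD patterns, a
    hyperellipse recognition score for projected trajectories, direct
    classification baselines (support vector machines, RUSBoost, Infomax
    independent component analysis), peri-stimulus time histogram
    conversion and plain-text collection I/O, and a seeded synthetic
    generator of benchmark-like neural population recordings for testing
    every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    rpart,
    ica
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
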