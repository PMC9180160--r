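Package: clpsosvm
Title: Swarm-Optimized Support Vector Classification of Near-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end chemometrics pipeline for multi-class classification of
    near-infrared (NIR) spectra, built around RBF-kernel support vector machines
    whose penalty parameter c and kernel width g are tuned by particle swarm
    optimization (PSO) or comprehensive-learning particle swarm optimization
    (CLPSO). Provides a spectra container with absorbance/transmittance
    conversion and replicate averaging, Savitzky-Golay smoothing, PCA feature
    extraction, an explicit one-vs-rest max-score multiclass scheme, a NIPALS
    PLS-DA baseline classifier, a generator of tea-like synthetic NIR spectra,
    and a stratified rotation-fold evaluation protocol with PC-count sweeps and
    four-method comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
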