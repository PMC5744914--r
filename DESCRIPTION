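Package: olivesim
Title: Physiological Point-Neuron Models of the Lateral Superior Olive
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for binaural neurons of the lateral superior
    olive (LSO). Provides a common phase-locked inhomogeneous-Poisson input
    stage (amplitude-modulated and unmodulated tone stimuli), seven
    point-neuron models of increasing biophysical complexity (coincidence
    counting, exponential and alpha Stein shot-noise models, passive and
    active integrate-and-fire models, and original and adjusted
    Wang-Colburn Hodgkin-Huxley-type models with Rothman-Manis channel
    kinetics), and the monaural/binaural tuning metrics and membrane
    characterization protocols (rate and synchrony modulation transfer
    functions, binaural envelope-phase and interaural-level-difference
    tuning, impedance, current-voltage and step-current protocols) used to
    calibrate and compare the models against targeted output-rate ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
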