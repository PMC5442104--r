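Package: radca
Title: Cellular-Automaton Simulation of Tumour Response to Fractionated
    Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lattice (cellular-automaton) simulator of tumour response to
    fractionated radiotherapy. Tumours grow on a 2D pixel grid by an
    n-layer morphological division rule; steady-state oxygen fields are
    derived from a random vessel map by Gaussian filtering; radiation kills
    tumour cells through the linear-quadratic model with a Howard-Flanders
    hypoxia reduction factor, condemning cells to mitotic catastrophe; and
    vessels respond to dose by increased leakiness (perfusion) or death.
    Monte Carlo cohorts of in-silico mice yield tumour control probability
    (TCP) curves, sigmoid fits, and TCP50 estimates with confidence
    intervals. Calibration utilities fit oxygen-versus-distance profiles,
    Howard-Flanders hypoxia curves, leak factors, and growth-layer counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
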