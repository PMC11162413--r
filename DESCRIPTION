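Package: macchiato
Title: Design Automation for Spatial Bacterial Logic Gates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing digital logic devices built from bacterial
    colonies reading additive morphogen gradients. Receiver colonies convert
    the local concentration of a diffusible signal into a fluorescent output
    through threshold activation functions (highpass, lowpass, bandpass,
    bandstop); the logic gate a receiver computes is set by its position
    relative to the signal sources. The package represents truth tables and
    their hex gate codes, enumerates the digital functions realizable by a
    single receiver on the additive signal-concentration axis via
    linear-feasibility search, minimizes arbitrary truth tables into the
    smallest receiver set under implicit-OR semantics (the Macchiato
    algorithm), simulates the two-dimensional reaction-diffusion device with
    colony growth and Hill-type dose-response dynamics, and optimizes the
    physical placement of inputs and receivers on a microtiter-plate lattice
    with an evolutionary algorithm. Includes synthetic characterization-data
    generation and dose-response fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    quadprog,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
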