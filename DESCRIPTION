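Package: ceasim
Title: Simulation and Reconstruction for Concurrent Excitation and
    Acquisition MRI with Active Analog Cancellation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator and reconstruction toolkit for
    concurrent excitation and acquisition (CEA) MRI. Models the analog
    self-interference cancellation chain (directional coupler,
    voltage-controlled phase shifter and attenuator, power-combiner
    subtraction), an automated coordinate-descent feedback loop that
    calibrates the canceller against a simulated transmit-to-receive
    coupling channel, frequency-swept transmit pulses (edge-smoothed chirp
    and HS8 hyperbolic secant), small-tip spin simulation of radial CEA
    acquisitions with a Bloch-equation oracle, digital removal of residual
    frequency-dependent transmit leakage, and image reconstruction by
    pseudo-inverse deconvolution of the per-spoke free induction decay
    followed by Kaiser-Bessel gridding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
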