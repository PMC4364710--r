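Package: dualTRghost
Title: Simulation of the Dual-TR Ghost Artifact in Saturated Turbo-FLASH MR
    Angiography
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic simulation toolbox for the half-FOV ghost artifact
    that arises when a spoiled gradient-echo (turbo-FLASH) sequence is run with
    two alternating effective repetition times, as happens when a venous
    saturation block precedes only every second excitation. Provides the
    closed-form dual-TR steady-state signal model and its two-flip-angle
    generalization, an independent Bloch fixed-point oracle, synthetic
    flip-angle phantoms, centered unitary Fourier transforms, the k-space
    assembly schemes (line interleaving, center-line correction factor,
    low-pass-style phase-encode reordering, zero filling), a numerical
    flip-angle adaptation solver, actual flip angle imaging (AFI) map
    estimation, and quantitative artifact metrics (ghost-to-source curves,
    signal-ratio curves, ringing amplitudes, Gibbs-style oscillation measures).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
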