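Package: photonstim
Title: Analysis of Evanescent-Field Optogenetic Stimulation on Photonic Waveguide Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for biohybrid photonic platforms that
    stimulate cultured neurons through the evanescent field of low-index-contrast
    polymer waveguides. Provides closed-form evanescent-field optics and slab
    dispersion solving, a semi-vectorial finite-difference mode solver for rib
    waveguides (effective indices, surface power densities, penetration depths,
    Gaussian fiber overlap integrals), fluorescent-bead TIRF calibration of the
    evanescent penetration depth, per-pixel FFT harmonic scoring of
    stimulation-locked calcium responses, cut-back propagation-loss regression
    with coupling/bend decomposition, and synthetic-data generators with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
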