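Package: pdeva
Title: Vibrational Pseudo-Spectrum Descriptors and Odorant Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds EigenVAlue (EVA) and Peak-Decomposed EVA (PD-EVA)
    vibrational pseudo-spectrum descriptors from discrete molecular
    vibrational frequencies, decomposes them into broad Gaussian
    components labelled by vibrational mode type, compares molecules with
    the Hodgkin similarity index, and groups them into physical
    (vibrational) classes by spectral clustering on the similarity
    matrix.  Includes a scalar ball-and-spring harmonic model that maps a
    molecular graph (atom masses, bond stiffnesses) to its vibrational
    spectrum through the mass-weighted stiffness Laplacian, a bundled
    reference set of 20 odorant molecules in 6 perceptual odour classes,
    and a synthetic odorant-class generator for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    jsonlite,
    minpack.lm,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
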