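Package: axonsm
Title: Validation of the White-Matter Standard Model Against 3D Axon Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate Standard Model (SM) parameters of diffusion MRI in
    white matter against axon-level morphometry. Generates synthetic populations of
    myelinated-axon skeletons with controllable orientation dispersion, undulation and
    beading; computes histology-style metrics (fiber orientation distribution and its
    rotational invariants, dispersion angle, intra-axonal volume fraction, axial
    tortuosity, predicted intra-axonal diffusivity); simulates multi-shell PGSE signals
    by spherical convolution of the fiber orientation distribution with the SM kernel;
    estimates SM parameters with four estimators (WMTI, NODDI, SMT, SMI); and compares
    the two arms with correlation statistics (Pearson with Fisher confidence intervals,
    Benjamini-Hochberg FDR, Lin's concordance).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
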