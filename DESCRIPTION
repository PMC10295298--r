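Package: hsiDetect
Title: Spectral Detection and Kinetic Trace Extraction for
    Excitation-Scanning Hyperspectral Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis framework for excitation-scanning hyperspectral
    fluorescence microscopy of live-cell signaling. Provides flat spectral
    response correction of excitation-scanned image stacks, construction of
    peak-normalized endmember spectral libraries from single-label controls,
    four pixel-wise spectral detection algorithms (non-negatively constrained
    linear unmixing, spectral angle mapper, constrained energy minimization,
    and matched filter), a theoretical sensitivity analysis that injects known
    amounts of a target endmember to yield sensitivity curves, positive-pixel
    curves, ROC curves and a minimum detectable limit, and pixel-filtered
    extraction of whole-field and single-cell time traces from time-lapse
    detection maps. A synthetic scene generator with known ground-truth
    abundances makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tiff,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
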