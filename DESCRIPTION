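Package: conewell
Title: Microwell-Array Time-Lapse Analysis for Clone Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for analyzing time-lapse images of conical
    microwell arrays used in single-cell clone discovery. Detects and tracks
    microwell lattices in brightfield stacks, counts cells per microwell and
    quantifies their surface-marker fluorescence, estimates clonal growth
    rates with a dual-parameter proliferation gate, quantifies cytokine
    secretion rings with a rotational-symmetry false-positive filter, applies
    hierarchical gates to produce robotic pick lists, and models Poisson
    single-cell loading statistics and antigen-library enrichment. A seeded
    synthetic scene generator emulates the instrument output (OME-NGFF zarr,
    TCZYX) with complete ground truth, so that every stage of the pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
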