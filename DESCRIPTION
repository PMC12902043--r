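Package: holopollen
Title: Lens-Less In-Line Holographic Reconstruction and Pollen
    Classification Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for lens-less digital in-line holographic microscopy
    (DIHM) of pollen slides. Implements scalar-diffraction wave
    propagation by the angular spectrum method, hologram normalisation,
    single backpropagation, iterative Gerchberg-Saxton phase retrieval
    with object- and sensor-plane constraints for twin-image
    suppression, and automated refocus-distance selection by a
    Tamura-of-gradient sharpness score. Includes a synthetic-data
    generator that renders stylised pollen phantoms for six allergenic
    species, forward-simulates their holograms with shot/read noise and
    12-bit quantisation, and draws two-evaluator classification
    records from per-modality confusion structures. Evaluation
    statistics cover per-evaluator and pooled accuracy, confusion
    matrices, per-class F1 and Cohen's kappa for inter-observer and
    inter-modality agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    png,
    yaml,
    jsonlite,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
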