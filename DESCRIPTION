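Package: RipeFuse
Title: Feature-Level Fusion of Image, Vis/NIR Spectral, and Haptic Data for
    Tomato Maturity Classification
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tri-modal feature-level fusion pipeline for non-destructive
    tomato maturity grading. Combines RGB images, visible/near-infrared
    transmission spectra (350-1100 nm, white/dark reference corrected), and
    100 Hz grip-pressure traces from a robotic gripper. Provides a calibrated
    synthetic tomato-phantom generator (three maturity stages plus
    heterogeneous internal/external ripening categories), the three modality
    preprocessing steps (threshold segmentation to 150x150, black-and-white
    spectral correction, zero-phase Butterworth low-pass filtering), a
    VGG16-style image extractor (8192-dim tap), a 1-D CNN spectral extractor
    (10-dim tap), an LSTM haptic extractor (64-dim tap), feature splicing to
    an 8266-dim vector, a fully connected residual classification network,
    and the accuracy/precision/recall evaluation protocol with confusion
    matrices. All networks run on a compact in-package neural engine; no
    external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RipeFuse-package.R'
    'utils.R'
    'phantom-config.R'
    'phantom-generate.R'
    'phantom-io.R'
    'preprocess.R'
    'nn-layers.R'
    'nn-network.R'
    'features.R'
    'fusion.R'
    'evaluation.R'
    'pipeline.R'
    'spectral-peaks.R'
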