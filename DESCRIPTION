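Package: spvtools
Title: Simulated Prosthetic Vision Stimulus Generation and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulated prosthetic vision (SPV) research on indoor
    scene understanding. Generates processed stimulus images from scenes by
    three methods (direct luminance, Canny edge baseline, and a schematic
    representation composed of structural informative edges with object masks
    and silhouettes), renders them through a configurable phosphene simulator
    (grid sampling, luminance quantization, electrode dropout, Gaussian dot
    rendering), reads and writes scene annotations with instance masks, builds
    synthetic indoor scenes with exact ground truth, and schedules and scores
    psychophysics experiments including recall/precision confusion matrices
    with a not-answered category.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    grDevices,
    graphics,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
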