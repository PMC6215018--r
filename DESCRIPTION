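Package: hilosect
Title: HiLo Optical Sectioning for Widefield Fluorescence Mesoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Optical-sectioning reconstruction for widefield fluorescence
    images acquired under paired uniform and laser-speckle illumination
    (HiLo microscopy). The low spatial frequencies of the in-focus signal
    are recovered by weighting the uniform image with the local contrast
    of the bandpass-filtered speckle/uniform difference image; the high
    frequencies come from a Gaussian high-pass of the uniform image; the
    two are fused with a spectral matching factor into a single sectioned
    image. Includes a seeded simulator of speckle illumination, widefield
    defocus and tilted-layer/bilayer phantoms, characterization tools for
    section thickness (tilted-layer Gaussian-fit procedure), contrast
    improvement and speckle-leakage artifacts, plus TIFF stack I/O, tiled
    processing for very large frames, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    tiff,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
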