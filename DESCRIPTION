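Package: micropick
Title: Grid-Based Particle Picking and Segmentation Label Generation for Cryo-EM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for locating single particles in cryo-electron microscopy
    micrographs from per-pixel probability density maps. Implements a
    grid-based local-maximum picker with Gaussian candidate scoring and
    non-maximum suppression, automated generation of segmentation training
    labels by reprojecting a 3D reconstruction at refined Euler angles,
    reference implementations of the convolutional layer operations
    (including atrous convolution and its receptive-field arithmetic), a
    synthetic micrograph simulator with controlled signal-to-noise ratio,
    and evaluation metrics (pixel intersection-over-union, SNR,
    precision/recall from coordinate matching). Reads and writes MRC2014
    rasters and EMAN box, plain coordinate, and STAR particle tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    EBImage,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
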