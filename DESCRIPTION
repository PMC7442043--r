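Package: lfmepi
Title: 3D Localization for Light-Field Microscopy via Convolutional Sparse
    Coding on Epipolar-Plane Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-snapshot 3D localization of compact fluorescent sources
    (beads, neuronal somata) from raw light-field microscope images. Includes a
    scalar wave-optics forward model for microlens-array light-field microscopes
    (Debye objective wavefront, lenslet phase mask, Fresnel propagation to the
    sensor), automatic calibration of rotation angle, lenslet pitch and lenslet
    centers from an out-of-focus frame, decoding of raw frames into the
    two-plane-parameterized 4D light-field with sub-aperture and epipolar-plane
    image (EPI) views, SVD rank-one background removal for scattering tissue,
    synthesis of a depth-aware EPI dictionary, and source localization by
    convolutional sparse coding solved with ADMM in the Fourier domain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
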