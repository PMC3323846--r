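Package: blobpet
Title: Blob-Basis 3D PET Reconstruction on a Polar Grid with Folded Symmetries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for fully 3D positron emission tomography (PET) image
    reconstruction using overlapping Kaiser-Bessel spherical basis functions
    ("blobs") placed body-centred on a cylindrical polar grid. Models a
    polygonal dual-layer small-animal scanner, exploits its rotation and
    reflection symmetry group to fold the sparse system response matrix onto a
    single angular-axial wedge, and reconstructs line-of-response histograms
    with maximum-likelihood expectation-maximisation using either a
    transposed-matrix or a chunked scatter backprojection. Includes an analytic
    footprint projector and a geometric Monte Carlo projector for building the
    system matrix, simulators for standard image-quality and resolution
    phantoms with Poisson count statistics, and the usual figures of merit
    (coefficient of variation, contrast-to-noise ratio, correlation
    coefficient, full width at half maximum of point-source profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils,
    tibble,
    jsonlite,
    yaml,
    RNifti,
    pracma,
    ggplot2,
    generics,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
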