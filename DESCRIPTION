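Package: neuralmap
Title: Neural Representations of Cryo-EM Density Maps and Density Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits a continuous, differentiable representation of a cryo-EM
    density map by training one sinusoidal (SIREN) network per overlapping
    sub-region of the voxel grid, and blends the trained networks into a
    single queryable field for density and gradient at arbitrary Angstrom
    coordinates.  On top of the fitted field it extracts a density graph:
    seed points above a global threshold are walked uphill along the density
    gradient to local peaks, clustered, and connected by edges within twice
    the map resolution, yielding candidate atom or residue locations.
    Includes MRC/CCP4 map input and output, a Gaussian map simulator in the
    style of Chimera's molmap, a tri-linear baseline interpolator, and
    evaluation utilities (interpolation mean absolute error against a fine
    control grid; one-to-one node-to-atom matching with sensitivity,
    specificity and RMSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
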