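Package: vesselmesh
Title: Automated Vascular Image-to-Mesh Construction with Uncertainty
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building patient-specific vascular surface models from
    3D angiographic volumes. Provides synthetic branched-vessel phantoms with
    ground truth, a multiscale Laplacian-of-Gaussian segmentation network with
    Bayesian (variational) convolution kernels and a class-balancing patch
    gate, isosurface extraction with uniform remeshing and regularised
    smoothing, diffeomorphic (LDDMM) surface deformation driven by image
    gradients with a Chebyshev graph-convolutional momentum predictor and an
    inlet/outlet scaling gate, segmentation and surface quality metrics
    (Dice, average surface distance, Hausdorff), and posterior-sampling
    uncertainty quantification propagated from voxels to surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    Matrix,
    igraph,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
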