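Package: lbptop
Title: Volumetric Texture Classification with Local Binary Patterns on
    Three Orthogonal Planes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Texture-based classification of 3D brain images using
    isotropic local binary patterns on three orthogonal planes (LBP-TOP).
    Reads and writes NIfTI-1 volumes and label volumes, resamples between
    isotropic resolutions, encodes per-voxel LBP codes on the xy/xz/yz
    planes with uniform-pattern mapping, aggregates atlas-parcellated
    histogram features, performs iterative SVM-weight feature selection
    with group merging, evaluates linear-SVM and 1-nearest-neighbour
    classifiers under nested 10-fold cross-validation, and assesses
    significance with permutation and McNemar tests.  A synthetic-phantom
    module generates seeded texture cohorts, masks, toy atlases and region
    timecourses so the full pipeline is exercisable without any imaging
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
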