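Package: surfmorph
Title: Surface-Based Multivariate Tensor Morphometry of Subcortical Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conformal rectangle parameterization of subcortical surface
    meshes via holomorphic 1-forms, inverse-consistent fluid registration of
    surface feature images in the parameter domain, multivariate tensor-based
    morphometry (log deformation tensors and areal Jacobians), medial-axis
    radial distances, and permutation-based group statistics with Hotelling's
    T2 and CDF-based false discovery rate control. Includes a synthetic
    cohort generator that produces two groups of putamen-like surfaces with
    known localized shape effects for validation and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
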