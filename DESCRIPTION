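Package: hapcage
Title: Patient-Specific Modelling of Porous Hydroxyapatite Interbody Fusion Cages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for CT-based patient-specific finite element modelling of
    vertebral bodies and 3D-printed porous hydroxyapatite interbody fusion cages.
    Generates synthetic vertebra phantoms with controllable trabecular texture,
    converts Hounsfield units to porosity through split linear calibration laws,
    estimates per-voxel stiffness directions with a gradient structure tensor,
    builds anisotropic elastic tensors from cylindrical-inclusion (cortical) and
    elongated Kelvin-cell foam (trabecular) micromechanics, designs FCC, Kelvin
    and Voronoi lattice scaffolds with uniform or radially graded porosity,
    homogenizes unit cells by periodic voxel finite elements, and runs
    linear-static tetrahedral finite element simulations with damage, fixation
    and macroscopic stiffness post-processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    fitdistrplus,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
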