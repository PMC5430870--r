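Package: gliomaRD
Title: Post-Surgery Glioma Growth Simulation with Treatment Effects and
    Brain Viscoelasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates post-surgery low-grade glioma growth on voxel grids
    with a reaction-diffusion model extended by DTI-guided anisotropic
    diffusion, a linear-quadratic radiotherapy loss, a tissue-heterogeneity
    weighted chemotherapy loss, and a Maxwell-Weichert viscoelastic stress
    contribution.  Includes a parametric brain-phantom generator (tissue
    labels, fiber-aligned tensor fields, resection cavities, therapy
    calendars), a stability-safe explicit finite-difference solver with a
    non-negativity oriented anisotropic stencil and no-flux brain boundary,
    and Jaccard/Dice overlap evaluation with an ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    withr
Config/testthat/edition: 3
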