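Package: osteofea
Title: Vertebral Strength Estimation from Quantitative CT by Finite Element Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for image-based vertebral biomechanics: generation of
    CT-like spine phantoms with calibration inserts, phantom-calibrated
    volumetric bone mineral density (vBMD) extraction, Hounsfield-unit
    based material mapping to transversely isotropic bone properties and
    strength limits, voxel-based tetrahedral meshing of segmentation
    masks, displacement-controlled nonlinear compression of single
    vertebrae and functional spinal units (vertebra-disc-vertebra
    assemblies) with failure-load extraction from the load-displacement
    curve, and covariate-adjusted partial-correlation analysis of the
    resulting cohort measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
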