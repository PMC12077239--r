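Package: condyleFE
Title: CT-Based Virtual Mechanical Testing of the Equine Distal Third
    Metacarpal Condyle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Subject-specific finite-element pipeline for virtual
    mechanical testing of the distal third metacarpal (MC3) condyle from
    calibrated computed tomography. Covers hydroxyapatite phantom
    calibration of CT numbers to radiological and ash density,
    region-aware density-modulus mapping with adaptive (sclerotic) and
    damage (lytic) factors, voxel-based tetrahedral meshing, a linear
    elastic solver for the standard condylar load case, extraction of
    mean maximum principal strain over the parasagittal-groove strip,
    grid-search tuning of the material factors against measured surface
    strain, and validation statistics for tuned versus non-tuned
    material models. Includes a synthetic phantom generator (calibration
    phantom and idealized condyles with sclerotic caps and focal lytic
    inclusions) used for verification and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
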