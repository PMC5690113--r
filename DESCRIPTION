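Package: rtprint
Title: Design-to-Print Conversion and QA for 3D-Printed Radiotherapy Beam Modifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts electron-bolus and proton-compensator designs into
    printable STL meshes and quality-assures the fabricated parts. Bolus
    contour stacks (DICOM RT Structure Set) are resampled, interpolated
    between CT slices and closed into watertight triangle meshes using
    Delaunay triangulation; compensator thickness grids (DICOM RT Ion Plan)
    are meshed as height fields. QA tools extract sub-pixel surface profiles
    from CT volumes, score geometric conformity as the per-slice largest
    Euclidean distance against the design, compute Hounsfield-unit
    uniformity inside an interface-eroded core, estimate mass density from
    weight and design volume, and estimate proton stopping power relative
    to water from the Bragg-peak pull-back of depth-dose curves. A synthetic
    module generates every input the pipeline consumes (parametric designs,
    minimal DICOM fixtures, voxelized CT volumes with noise and
    partial-volume blur, analytic Bragg curves) so the whole pipeline can be
    exercised without scanner or printer data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
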