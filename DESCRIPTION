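Package: ct2skin
Title: Triplanar Skin-Surface Point Clouds from Head CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reconstructs the outer skin surface of a head CT scan as a 3D
    point cloud without meshing or morphological preprocessing. A DICOM
    series is loaded into a Hounsfield-unit volume and resliced into axial,
    sagittal, and coronal stacks; each slice is binarized by in-range HU
    thresholding and passed through a chain of contour-validity filters
    (centroid gate, pixel connection, solidity, four-direction scan,
    row-crossing count, equipment-region check) that reject medical-equipment
    artifacts and intracranial noise. Validated contour points are projected
    into world millimeter coordinates from the DICOM geometry, fused across
    the three planes with two-stage voxel downsampling, and cleaned by radius
    and statistical outlier removal. Includes a synthetic DICOM head-phantom
    generator with analytic ground-truth surfaces, and evaluation tools:
    k-d-tree unique-point counting, trimmed-ICP rigid registration with RMS
    error, and one-sided coverage distance fields.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    RANN,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
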