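Package: chambervol
Title: Cardiac Chamber Volumetry from Surface Meshes and Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes cardiac chamber volumes from closed triangle surface
    meshes by signed tetrahedron (polygon) summation, and from binary
    segmentation masks by Simpson's-rule disk-area slice summation. Reads
    and writes STL surface meshes (ASCII and binary) with watertightness
    and orientation diagnostics, and NIfTI segmentation masks. Includes a
    synthetic ventricle phantom generator with known ground-truth volumes
    (bullet-shaped left ventricle, ellipsoid, crescent right ventricle,
    with seeded trabeculation fields), and a paired method-agreement
    toolkit: Lin's concordance correlation coefficient with confidence
    interval, Bland-Altman limits of agreement, paired mean squared error,
    paired t-test and Shapiro-Wilk normality check, bundled into a classed
    agreement object with print, summary and plot methods, plus an
    end-to-end phantom study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
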