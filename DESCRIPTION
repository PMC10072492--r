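Package: neckangle
Title: Direct CT-Based Measurement of Malrotation in Basicervical Femoral
    Neck Fractures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements and validates a geometric, computed-tomography based
    technique for measuring rotational displacement (anteversion/retroversion)
    across a basicervical femoral neck osteotomy, where the fractured neck can
    no longer serve as a pointer against the distal condylar plane. Provides a
    parametric voxel phantom of the proximal femur with a controllable
    medial-fragment rotation emulating a physical goniometer jig, the full
    measurement pipeline (neck-aligned oblique reformat, 5 mm axial slab,
    cortex contour extraction, supporting tangent, parallel line, least-squares
    and inscribed circle fits, intersection angle), and the reliability
    statistics used to validate it (per-level descriptives, two-way
    absolute-agreement intraclass correlation with F-based confidence
    intervals, Pearson correlation, paired t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: ImageProcessing, BiomedicalInformatics
RoxygenNote: 7.3.3
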