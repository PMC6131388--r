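Package: archtrough
Title: Dental Arch Shape and Panoramic Focal Trough Geometry from CBCT-Like Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic derivation of a standard dental and mandibular arch shape
    and the geometry of a panoramic focal trough (center, buccal and lingual
    boundaries, regional minimum thickness, and the dental-arch-to-ramus
    transition) from 3D cone-beam CT-like volumes. Implements intensity
    normalization, Frankfort-horizontal reorientation, removal of confounding
    regions, Otsu-based cumulative binarization of the mandible, axial
    maximum-intensity-projection arch images, canine-referenced cohort
    superimposition with area-matched thresholding, smoothing-spline curve
    fitting of the trough, and agreement statistics (dice, intraclass
    correlation). Includes a synthetic skull phantom generator with analytic
    ground truth so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti,
    png,
    igraph
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
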