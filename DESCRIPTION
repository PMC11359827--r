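Package: airwayseg
Title: Pulmonary Airway Tree Segmentation by Quasi-Spherical Region-Constrained
    Wavefront Propagation with Tracheal Wall Gap Sealing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments the bronchial tree in chest CT volumes by wavefront
    propagation (iterative one-layer morphological dilation with Hounsfield-unit
    threshold judgment) confined to adaptively sized quasi-spherical constraint
    regions grown from seed surfaces. Leakage through low-brightness tracheal
    wall gaps is detected inside each region, the gaps are localized by
    morphological closing differences and sealed by raising their CT values,
    and the threshold is adapted until a 200 HU cap. Includes a synthetic
    branching-tube CT phantom generator with voxel-exact ground truth,
    EXACT09-style completeness and leakage metrics, NIfTI and MetaImage volume
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
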