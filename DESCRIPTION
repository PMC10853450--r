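Package: cochleaPK
Title: Cochlear Perilymph Pharmacokinetics from Segmented Inner-Ear Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for physiologically based modelling of intratympanic drug
    delivery to the inner ear. Derives scala tympani cross-sectional geometry
    from segmented 3D fluid-space volumes by fitting a 3D logarithmic spiral
    and slicing perpendicular to it, simulates dexamethasone and dexamethasone
    sodium phosphate transport across the round window membrane into a 1D
    tapered perilymph duct (diffusion, first-order clearance, prodrug
    dephosphorylation, optional cerebrospinal-fluid inflow), and models
    sequential capillary sampling of perilymph from the round window. Includes
    a synthetic-data generator producing spiral-wound tapered-tube voxel
    phantoms with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
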