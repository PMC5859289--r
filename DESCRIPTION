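Package: morphotraj
Title: Kernel-Regression Growth Trajectories for Dense 3D Landmark Shape Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models continuous three-dimensional "growth curves" of dense
    corresponded landmark configurations (e.g. craniofacial surface scans
    sampled at template vertices) from cross-sectional data. Provides
    generalized Procrustes alignment with a robust option, symmetrization,
    kernel-weighted partial least-squares regression of shape and size on
    age, per-vertex growth vector fields and growth rates, two-group
    trajectory comparison (dimorphism-magnitude curves with permutation
    tests and bootstrap confidence intervals, per-vertex difference maps),
    age-adaptive binary classification with repeated stratified k-fold
    cross-validation, a synthetic cohort generator with known ground truth,
    and plain-text mesh (PLY/OBJ) and metadata I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
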