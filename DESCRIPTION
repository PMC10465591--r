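Package: canalrepro
Title: Reproducibility Analysis of Repeated Mandibular Canal Localisations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how reproducibly an automated system
    localises the mandibular canal across repeated cone beam CT scans of
    the same patient.  Implements 3D centerline and segmentation agreement
    metrics (symmetric mean curve distance, average symmetric surface
    distance, Dice coefficient), within-subject repeatability statistics
    (within-subject standard deviation and repeatability coefficient with a
    downward-corrected effective replicate count for unbalanced designs),
    and a Bayesian ordinal repeatability measure for Likert quality ratings
    based on a partial credit model with subject random effects.  A
    synthetic-cohort simulator with known ground truth exercises the full
    pipeline in the absence of clinical data, which is access-restricted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    rjags,
    coda,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
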