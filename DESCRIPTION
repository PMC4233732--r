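Package: masticate
Title: Multibody Biomechanics of Rabbit Mastication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rigid-body simulator and analysis pipeline for rabbit jaw
    biomechanics. Builds a musculoskeletal mandible model with Hill-type
    muscle strands (activation-scaled maximum force plus exponential passive
    tension), prescribes three-phase chewing kinematics (opening, fast
    closing, slow closing) with sagittal and frontal gape trajectories,
    models the food bolus as two rigid plates joined by a capped tri-axial
    spring, and recovers muscle activations at each timestep by solving a
    minimum-effort quadratic program subject to the six degree-of-freedom
    mandible force balance and unilateral temporomandibular joint contact.
    Reports bite-force components, per-muscle peak activations, recruited
    muscle fractions and maximum incisor bite force for comparison with
    in vivo measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    quadprog,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
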