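Package: femplate
Title: Femoral Morphometry Driven Design of Customized Bone Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts femoral morphological features from cohort parameter
    tables by principal component analysis (with sampling-adequacy tests,
    component retention rules, varimax rotation and variance-weighted
    composite scoring) and feeds them into a parametric feature model of a
    lateral proximal-femur ("eagle-shaped") locking plate: curve-topology
    constraints over a twelve-curve skeleton, a semantic parameter
    hierarchy, principal-component-weighted mapping from bone to plate
    parameters, lofting of the plate undersurface, solid extrusion with
    screw-hole layout, and point-to-surface fit-deviation reporting.
    Includes a synthetic-cohort and synthetic-femur generator so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
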