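Package: cflsim
Title: Rigid-Body Simulation of Calcaneofibular Ligament Strain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the lateral ankle as a two-axis rigid-body linkage
    (talocrural and subtalar hinges built from digitized anatomical
    landmarks) and computes percent strain of the calcaneofibular
    ligament (CFL) over a grid of plantarflexion/dorsiflexion and
    inversion/eversion poses.  Classifies ligaments into five
    running-angle morphology categories (CFL20, CFL30, CFL40, CFL50,
    CFL2), aggregates per-category strain tables, and provides a
    synthetic landmark generator (template ankle, prescribed running
    angles, two-bundle variants, digitizer noise, cohort sampling) so
    that every pipeline stage is testable without cadaver data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
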