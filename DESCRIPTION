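Package: ptmr
Title: Particle Tracking Microrheology and Sperm Kinematics in Mucus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Paired measurement workflow for cervical mucus: particle tracking
    microrheology (PTMR) converts thermal bead trajectories into mean squared
    displacement curves and viscoelastic spectra via the generalized
    Stokes-Einstein relation, yielding the complex viscosity eta*; a
    Crocker-Grier style detector and linker recovers trajectories from
    time-lapse image stacks; CASA-style kinematics (VSL, VCL, VAP, LIN, STR,
    ALH) summarize sperm motility; and dilution-series statistics relate
    log10 eta* to log10 sperm velocity (Anderson-Darling family selection,
    Pearson correlation, power-law fits). A Brownian-dynamics simulator with
    image rendering provides ground-truth fixtures for every stage.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml,
    nortest,
    png
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
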