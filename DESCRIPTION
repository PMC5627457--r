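Package: socialtrackr
Title: Automated Tracking and Behavioral Dynamics for Mouse Social
    Preference Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Video tracking and behavioral-dynamics analysis for
    two-chamber rodent social preference (SP) and social novelty
    preference (SNP) assays. Segments a dark subject mouse on a light
    arena floor, detects contact between the subject (body boundary or
    head) and two stimulus zones via body-based, head-directionality and
    wired-animal tracking algorithms, and converts the per-frame contact
    labels into gap-corrected investigation bouts, same-stimulus
    intervals and between-stimulus transitions. Computes per-session
    metrics (binned investigation time, relative duration of
    investigation (RDI), bout- and interval-duration distributions,
    transition dynamics, exploration/interaction phase summaries,
    open-field distance and center/periphery ratio) and pools them
    across animals. Ships a seeded behavior simulator and video renderer
    producing ground-truthed synthetic sessions, so the whole pipeline
    is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
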