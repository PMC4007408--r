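Package: axodyne
Title: Quantification of Axonal Mitochondrial Transport, Axonopathy Staging
    and Wallerian Degeneration Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vivo imaging of single axons with
    fluorescently labeled mitochondria, as used to study alpha-synuclein
    toxicity in zebrafish sensory neurons. Builds kymographs from time-lapse
    stacks along traced axon paths, extracts mitochondrial tracks, segments
    them into anterograde/retrograde runs and pauses, and applies the
    standard motility criterion (at least 2 micrometres at 0.1 micrometres
    per second). Provides mitochondrial morphometrics (density, length:width
    ratios), a configurable 5-point axonopathy staging rubric for axon
    intensity profiles, Wallerian-degeneration lag and clearance timing from
    sampled event series, cohort survival percentages, and the associated
    group statistics (unpaired t-tests, one-way ANOVA, Newman-Keuls
    post-test). A seeded synthetic-data generator emulates every
    experimental condition (time-lapse movies, morphology images, axon
    profiles, cohort and post-transection event tables) with exact ground
    truth, so every stage of the pipeline is testable without microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
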