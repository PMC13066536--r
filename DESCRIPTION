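Package: pulsevessel
Title: Pulsatile Vessel Dynamics in Free-Breathing Lung MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cardiac-driven pulsatile vessel expansion and
    flow-related signal enhancement in dynamic (2D+t) free-breathing lung
    MRI. Provides a synthetic dynamic-phantom generator with known cardiac
    and respiratory ground truth, classical per-frame lung and vessel
    segmentation baselines with a plug-in protocol for learned segmenters,
    extraction of pulsatile time-series metrics (coefficients of variation
    of vessel area, lung area and vessel signal, signal-to-expansion delay
    as a fraction of the RR-interval, heart rate), and the accompanying
    test-retest repeatability statistics (ICC(2,1), SEM, MDC, Bland-Altman,
    Friedman with Dunn-Sidak post hoc) and cohort-comparison statistics
    (Kruskal-Wallis with eta squared and Dunn-Sidak post hoc, Dubois body
    surface area, multivariable linear regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
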