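Package: bivakit
Title: Bio-Electrical Impedance Vector Analysis with Age- and
    Sex-Standardised Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for bio-electrical impedance vector analysis (BIVA) in
    children and adolescents: quality control of duplicate 50 kHz
    resistance/reactance/phase-angle readings, height-adjusted vector
    components, 4-component body composition and fat-free-mass hydration,
    LMS (Box-Cox) age- and sex-conditional reference fitting with
    standard deviation scores, bivariate confidence and tolerance
    ellipses on the RXc plane with Hotelling's T2 tests, cohort-level
    correlation, regression and group-contrast analyses, and a synthetic
    cohort generator with a configurable standard-deviation-score
    correlation structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
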