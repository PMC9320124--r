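Package: codaspectrum
Title: Compositional Analysis of the Physical Activity Intensity Spectrum
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for compositional data analysis of accelerometer-derived
    physical activity intensity spectra in youth cohorts. Converts epoch-level
    wrist acceleration (ENMO) into nine-band daily time-use compositions over a
    standardised 960-minute waking day, fits ordinary least-squares regressions
    of BMI z-score on rotated pivot-coordinate isometric log-ratios of the
    composition, and performs one-for-remaining compositional isotemporal
    substitution with delta-method confidence intervals. Includes a seeded
    synthetic cohort generator for end-to-end testing, cohort exclusion-cascade
    utilities, and reporting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
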