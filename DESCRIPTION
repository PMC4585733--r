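Package: plateletdepo
Title: Modelling and Cross-Validated Prediction of Platelet Deposition in a Perfusion Chamber
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three complementary approaches to predicting platelet deposition
    measured in an ex vivo (Badimon-type) perfusion chamber: a mechanistic
    mass-transfer boundary-layer model with two-layer first-order adhesion
    kinetics and grid-search calibration of the kinetic constants, a
    phenomenological log-log power-law regression, and a repeated
    random-forest baseline with a post-hoc linear correction. Includes a
    synthetic perfusion-experiment generator, leave-one-subject-out
    cross-validation with median-relative-error scoring, and delimited-text
    readers and writers for perfusion tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
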