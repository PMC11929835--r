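Package: skintact
Title: Skin Physiology, Tactile Friction, and Perception Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how finger-pad skin physiology (stratum
    corneum hydration and thickness, cutometer deformability parameters,
    Meissner corpuscle density, age) relates to tactile friction and
    perception of structured materials. Includes extraction of friction
    coefficients from raw three-axis force traces, micropillar and
    self-affine rough-surface geometry models, principal component
    analysis with varimax rotation and sampling-adequacy diagnostics,
    multiple regression with Johnson relative weights, Weibull
    psychometric fitting with just-noticeable-difference estimation,
    bootstrap confidence intervals, and a synthetic-cohort generator
    that emulates the statistical structure of a tactile-psychophysics
    study so every analysis stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
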