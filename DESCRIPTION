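Package: uvsdr
Title: Unequal-Variance Signal Detection Modelling of Recognition Confidence Ratings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood fitting of the unequal-variance signal
    detection (UVSD) model to 6-point recognition confidence ratings,
    including a four-distribution extension for mixed-list designs with
    shared decision criteria. Provides ROC and z-ROC computation, synthetic
    data generators for whole recognition experiments (encoding-variability
    and strength-scaling modes, synthetic word-norm lexicons), constrained
    stimulus-list sampling with normality checks, parameter-recovery
    studies, and the accompanying statistical battery (repeated-measures
    ANOVA with Greenhouse-Geisser correction, sequential polynomial
    scaling-curve fits, manipulation-check regressions, paired-t power).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
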