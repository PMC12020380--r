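Package: phetraj
Title: Matched-Cohort PheWAS and Disease-Trajectory Analysis for
    Longitudinal Diagnosis Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for studying the comorbidity burden of an index
    condition in longitudinal electronic health records: propensity-score
    matched cohort assembly, phenome-wide association screening with
    stratified Cox models, Fine-Gray competing-risk screening of causes of
    death, landmark (time-window) hazard estimation, and construction of
    directed disease-trajectory graphs via exact binomial directionality
    tests, adjusted odds ratios and bootstrap mediation analysis. Includes
    a synthetic electronic-health-record generator with known ground truth
    so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    igraph,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cmprsk,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
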