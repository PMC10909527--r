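Package: affectspace
Title: Joint Dimensional Analysis of Autonomic and Subjective Emotion Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and tests a common autonomic-subjective affective space from
    trial-level psychophysiological data. Provides a synthetic trial-table and
    raw-signal generator with a planted two-factor latent structure and crossed
    participant/stimulus random effects; preprocessing of pupillometry (blink
    interpolation, subtractive baseline correction), skin conductance
    (trough-to-peak phasic amplitude) and heart-rate change scores; trial-level
    linear mixed models with crossed random intercepts; a from-scratch Multiple
    Factor Analysis with group weighting, partial points, partial axes and
    supplementary projections; hierarchy-respecting cluster-bootstrap confidence
    intervals and stratified permutation tests for the eigenstructure; and
    random-forest / k-means validation of the retained dimensions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    randomForest,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
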