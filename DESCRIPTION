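Package: cvtscreen
Title: Cardiac Vagal Tone Processing and Screening Analytics for
    Cardiovascular Autonomic Neuropathy
Version: 0.1.0
Authors@R:
    person("Maintainer", "CVT", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing overnight beat-to-beat cardiac vagal tone
    (CVT) recordings as a screening biomarker for cardiovascular autonomic
    neuropathy (CAN) in diabetes. Provides a synthetic cohort generator with
    hierarchical subject/night structure, sleep-stage CVT modulation, beat
    dropouts and heart-rate artifacts; a beat-series file dialect with
    readers and writers; the standard preprocessing chain (rolling average,
    edge trimming, artifact excision, signal-quality filtering, retention
    gating); per-recording CVT summaries including the CVT-capacity
    statistic; night-to-night reliability via random-intercept variance
    components and the intraclass correlation coefficient; and diagnostic
    performance evaluation (ROC, AUC with DeLong confidence intervals,
    Youden-index cut-offs, predictive values) of CVT biomarkers against CAN
    staging from cardiovascular autonomic reflex tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
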