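Package: icebergscreen
Title: ICEBERG Geriatric Emergency-Room Screening Score and Validation Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scoring engine for the ICEBERG screening instrument, a nine-domain
    additive questionnaire (total score 1 to 30) that flags older emergency-room
    patients (age 70+) likely to need geriatric consultation. The package ships
    the instrument definition as a declarative config, scores patient response
    sets with configurable handling of missing items, and dichotomizes totals at
    the median-derived cut-point (high >= 10 vs low < 10). Two validation
    pipelines reproduce the structure of the instrument's pilot studies:
    construct validity (rank-sum, t and chi-square comparisons of Comprehensive
    Geriatric Assessment components between risk classes, plus Spearman
    score-component correlations) and criterion validity (contingency summaries,
    age- and sex-adjusted logistic odds ratios for acute-care outcomes, and
    rank-based comparisons of length of stay and nursing workload). A synthetic
    cohort generator with a single latent frailty factor, calibrated to the
    published pilot marginals, supports power, calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
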