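Package: lexisapc
Title: Age-Period-Cohort Analysis of Method-Specific Suicide Mortality
    with Death-Record Correction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for ecological time-trend analysis of cause-specific
    mortality on a Lexis grid. Corrects death-record tables for intent
    misclassification (proportional redistribution of garbage-coded
    deaths) and registration under-coverage, computes age-specific and
    direct-standardized rates with triennial smoothing, assembles
    five-year age by period Lexis tables with synthetic birth cohorts,
    and fits Poisson age-period-cohort models identified through
    estimable functions: annual drift with trend classification, and
    detrended period and cohort relative risks against reference
    categories. Includes a synthetic vital-registration data generator
    with a known age-period-cohort surface, intent misclassification
    and coverage thinning, so the whole pipeline is testable against
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
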