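Package: dischargesat
Title: Scoring and Mode-of-Administration Analysis of a Hospital Discharge
    Satisfaction Questionnaire
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a 17-question patient satisfaction instrument for the
    hospital discharge process: three item subscores (discharge logistics
    organization, preplanned posthospital continuity-of-care organization,
    patient impressions at discharge) computed as normalized sums over
    applicable questions, and their mean as a total score in [0,1].
    Provides exact and tie-corrected nonparametric tests (Fisher's exact
    test, Mann-Whitney-Wilcoxon, Wilcoxon signed rank) with enumeration
    p-values for small samples, Bonferroni-adjusted arm comparisons and
    percentile tables, a synthetic cohort generator emulating a randomized
    Internet-versus-telephone survey with arm-specific nonresponse, and a
    reporting pipeline with exact flow accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
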