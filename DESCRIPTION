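Package: pdscore
Title: Preoperative Risk Scoring and Outcome Validation for Pilonidal Disease
Version: 0.1.0
Authors@R: person("pdscore", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Implements the Hazem-Talaat additive preoperative severity score
    for pilonidal disease (nine clinical and anatomical factors, totals 10-27,
    high risk at >= 21) together with the statistical machinery used to
    validate such a score on a surgical cohort: descriptive summaries,
    Shapiro-Wilk normality gating, Pearson chi-square with Fisher-exact and
    Monte-Carlo fallbacks under the 20% expected-count rule, pooled-variance t
    and Mann-Whitney tests, ROC curve construction with AUC, Hanley-McNeil
    confidence intervals, Youden-optimal cutoffs and diagnostic metrics.
    Ships a deterministic 156-patient reconstruction fixture matching the
    published group-conditional counts, stochastic cohort simulators
    (outcome-conditional and prospective logistic-link modes), cohort CSV
    input/output and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
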