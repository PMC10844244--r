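Package: bopmeta
Title: Burden-of-Proof Meta-Analysis of Dichotomous Risk Factors
Version: 0.1.0
Authors@R:
    person("bopmeta", "maintainers", email = "maintainers@bopmeta.org",
           role = c("aut", "cre"))
Description: Mixed-effects meta-regression of log relative risks for
    dichotomous exposures with least-trimmed-squares outlier trimming,
    stepwise-Lasso selection of binary bias covariates, Fisher-information
    uncertainty for between-study heterogeneity, conservative
    Burden-of-Proof Risk Function (BPRF) scoring with star ratings, and
    Egger-regression publication-bias diagnostics. Includes a synthetic
    observation generator with known truth for validation, a per-outcome
    pipeline with sensitivity grids, and forest/funnel reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rlang,
    stats,
    utils,
    glmnet,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
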