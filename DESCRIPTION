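Package: hfvuln
Title: Health Financing Vulnerability Scoring for External Aid Shocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct composite health-financing vulnerability scores for
    countries exposed to reductions in external (donor) health funding.
    Assigns ordinal exposure levels to four health-financing and macro-fiscal
    factors (current health expenditure per capita, foreign aid dependency,
    budget space potential, capacity to borrow), derives factor weights by
    principal component analysis of the polychoric correlation matrix of the
    ordinal levels (with exploratory factor analysis, entropy and equal
    weighting as sensitivity alternatives), aggregates the weighted normalized
    levels into a 0-100 vulnerability score with archetype categories, and
    provides validity and method-agreement diagnostics. Includes a synthetic
    data generator (thresholded correlated latent Gaussian factors) so the
    whole pipeline is testable offline, and the published 47-country WHO
    African Region reference dataset reconstructed from its printed weighted
    component scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
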