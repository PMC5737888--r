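Package: cquaids
Title: Censored Quadratic Almost Ideal Demand Systems and Beverage Tax
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of censored Quadratic Almost Ideal Demand Systems
    (QUAIDS) from household expenditure surveys.  Quality-adjusted cluster
    prices are recovered from unit values, a control-function residual
    absorbs total-expenditure endogeneity, per-group probit participation
    models feed a Shonkwiler-Yen two-step censoring correction, and the
    augmented nine-equation share system is estimated by iterated feasible
    generalized least squares under adding-up, homogeneity and symmetry
    restrictions.  Censoring-adjusted uncompensated price elasticities are
    evaluated at sample means with nonparametric bootstrap standard errors.
    A projection module converts an own-price elasticity and a baseline
    sales forecast into post-tax prices, volumes and fiscal revenue for an
    ad-valorem tax on sugar-sweetened beverages.  A synthetic survey
    generator with a known data-generating process supports parameter and
    elasticity recovery studies.
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
    ggplot2,
    optparse
Config/testthat/edition: 3
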