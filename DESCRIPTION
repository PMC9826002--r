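Package: vaxmono
Title: Monotone Geostatistical Mapping of Multi-Dose Vaccination Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian binomial geostatistical modelling of multi-dose
    vaccination coverage with the monotonicity constraint p1 >= p2 >= p3
    enforced by construction. Implements the conditional-probability (CP)
    and ratio-based (RB) indicator constructions, a Matern Gaussian random
    field with an iid nugget on the logit scale, penalized-complexity
    priors on the covariance parameters, MCMC posterior sampling,
    kriging-based prediction to a grid, k-fold cross-validation metrics,
    population-weighted admin-level aggregation, dropout rates and
    zero-dose counts, plus a synthetic-data generator emulating cluster
    survey designs for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
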