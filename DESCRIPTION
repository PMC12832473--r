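Package: foodineq
Title: Socio-Economic Inequality in Household Food Security
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring and decomposing socio-economic inequality in
    binary household food-security outcomes from complex-survey data.
    Provides a harmonized "no household hunger" outcome, survey-weighted
    prevalence estimates with logit-scale confidence intervals,
    probability-weighted logistic and linear-probability regression with
    robust (sandwich) inference and a diagnostic suite (link test,
    Hosmer-Lemeshow, ROC/AUC, variance inflation factors), rank-dependent
    concentration indices (standard, Erreygers, Wagstaff) with
    convenient-regression and bootstrap standard errors, Wagstaff-van
    Doorslaer regression-based decomposition of the index into factor
    contributions, and a seeded synthetic generator emulating multi-wave
    household surveys with wealth quintiles and heterogeneous probability
    weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
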