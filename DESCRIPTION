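Package: nonhdlrisk
Title: Lifetime Cardiovascular Risk Modelling for Non-HDL Cholesterol Under
    Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate the long-term association of non-HDL
    cholesterol with atherosclerotic cardiovascular disease in pooled
    multi-cohort data under the competing risk of death from other causes.
    Provides a seeded synthetic-cohort generator with cause-specific
    Weibull event times on the age scale; lipid preparation (unit
    conversion, treatment inflation, guideline threshold categories);
    Aalen-Johansen cumulative incidence and Gray's test; cohort- and
    sex-stratified Cox models on the age timescale with categorical,
    interaction and spline codings of non-HDL cholesterol; absolute
    probability of a cardiovascular event by age 75 from cause-specific
    Cox models with parametric Weibull baseline hazards, averaged into
    sex by age-group by lipid-category by risk-factor-burden cells; a
    treatment-benefit model of hypothetical 30 or 50 percent non-HDL
    reduction (treated probabilities, risk differences, numbers needed
    to treat, relative risk reduction, monotone treated incidence
    curves); and derivation/validation utilities (within-cohort splits,
    cell-probability RMSE, cross-validated concordance, pseudo-value
    calibration curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    survival,
    cmprsk,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
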