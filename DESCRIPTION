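Package: durvaCEA
Title: Cost-Effectiveness Model of Durvalumab Consolidation in Stage III NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dynamic three-state (progression free, progressed disease, death)
    state-transition model for the cost-effectiveness of durvalumab consolidation
    versus best supportive care in unresectable stage III non-small cell lung
    cancer from the Chinese healthcare-system perspective. Provides parametric
    survival curves (exponential, Weibull, log-normal, log-logistic, Gompertz,
    generalized gamma) with censored maximum-likelihood fitting and AIC/BIC
    selection, a semi-Markov cohort engine with post-progression tunnel states on
    a 14-day/28-day cycle grid, drug-acquisition costing with vial wastage and a
    staged patient-assistance program, discounted life-year/QALY/ICER synthesis,
    one-way and probabilistic sensitivity analysis (tornado, CEAC), and a
    synthetic individual-patient-data generator for right-censored survival times
    and patient-clustered EQ-5D utility observations.
License: MIT
Encoding: UTF-8
Imports:
    flexsurv,
    survival,
    lme4,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
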