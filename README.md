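# durvaCEA

Cost-effectiveness modelling of durvalumab consolidation versus best
supportive care (BSC) in unresectable stage III non-small cell lung cancer,
from the Chinese healthcare-system perspective.

Consolidation durvalumab after chemoradiotherapy prolongs progression-free
and overall survival but at a high acquisition cost, partially relieved in
China by a staged Patient Assistance Program (PAP). This package implements
the full decision model for that trade-off, for health-economic analysts
who want every assumption inspectable, testable and swappable:

* **Parametric survival curves** — exponential, Weibull, log-normal,
  log-logistic, Gompertz and generalized gamma, with censored
  maximum-likelihood fitting and AIC/BIC selection. The generalized gamma
  uses the location/scale/signed-shape form: for `Q < 0`,
  `S(t) = P(Q^-2, Q^-2 exp(Q (ln t - mu)/sigma))` with `P` the regularized
  lower incomplete gamma function; the published shape column `k` maps to
  `Q = -k` (a documented, falsifiable convention switch).
* **A semi-Markov three-state cohort engine** (progression free → progressed
  disease → death) on the trial's cycle calendar — 26 fourteen-day cycles,
  then 28-day cycles to 40 years — with post-progression survival clocked
  from progression via tunnel cohorts, and per-cycle transition
  probabilities `1 - S(t1)/S(t0)`.
* **Costing** with exact vial arithmetic (wastage paid), the PAP
  pay-2 / free-2 / pay-4 / free-thereafter schedule, state-occupancy
  resource costs, subsequent-treatment mix and terminal care.
* **Health-economic synthesis** — discounted LY/QALY at 5%/year, ICER,
  net monetary benefit against the ¥212,676/QALY threshold (3× 2019 GDP
  per capita).
* **Sensitivity analysis** — tornado-ordered one-way analysis and a
  seeded 1,000-draw probabilistic sensitivity analysis with
  moment-matched gamma/beta/normal/uniform distributions and a
  cost-effectiveness acceptability curve.
* **A synthetic-data generator** for right-censored TTP/PFS/PPS times and
  patient-clustered longitudinal utility observations, so the fitting and
  estimation machinery is fully testable without the (non-public) trial
  data.

## Worked example

```r
library(durvaCEA)

# post-progression survival: log-normal, median e^3.0448 = 21.0 months
pps <- surv_curve("lognormal", c(meanlog = 3.0448, sdlog = 1.1876))
median_survival(pps)
#> [1] 21.00583

# one administration: 10 mg/kg x 61.2 kg = 612 mg -> one 500 mg + one 120 mg vial
administration_cost(612, vial_set(c(120, 500), c(6066, 18088)))
#> [1] 24154

# base case, durvalumab arm
cfg  <- default_config()
grid <- do.call(build_cycle_grid, cfg$grid)
run_cohort(build_arm(cfg, "durvalumab"), grid)$econ
#> <econ_result> discount 5.0%
#>   LY   PF 7.0031  PD 1.6317  total 8.6348 (undisc 16.4369)
#>   QALY PF 6.3098  PD 1.4082  total 7.7179 (undisc 14.7204)

# two-arm comparison with assistance-program drug pricing
runner <- make_model_runner(default_config(pap = TRUE))
runner()$comparison
#> <cea_comparison> dCost 75064.95 RMB, dQALY 3.2353, dLY 3.5694
#>   ICER = 23201.82 RMB/QALY; NMB at WTP 212676: 613006.64 RMB; cost-effective: TRUE
```

The first block evaluates the shared post-progression survival curve and
the exact vial cost per administration. The cohort run reports discounted
person-time: the durvalumab cohort accrues 7.00 discounted life-years
progression free and 1.63 after progression, weighted by utilities 0.901
and 0.863 into 7.72 QALYs. The comparison line prices both arms —
**with placeholder resource-use costs**: the quantities behind medical
service, inspections, subsequent treatment and adverse events were never
published, so the shipped values are illustrative and the cost/ICER
figures above change as soon as real inputs are supplied (see
`vignettes/model-methods.Rmd`). LY/QALY outputs are unaffected by the
cost placeholders.

Orchestrated runs write CSV outputs plus a manifest that lists every
placeholder value:

```r
run_base_case(default_config(), "out/base")           # traces, econ, costs, comparison
run_owsa_analysis(default_config(), "out/owsa")       # tornado.csv
run_psa_analysis(default_config(), "out/psa", seed = 1)  # samples, CEAC, summary
```

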