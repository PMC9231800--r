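---
title: "Model and methods: durvalumab consolidation cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: durvalumab consolidation cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(durvaCEA)
```

## The decision problem

Durvalumab consolidation after platinum-based chemoradiotherapy prolongs
progression-free and overall survival in unresectable stage III non-small
cell lung cancer, at a high drug-acquisition cost. This package implements
the full decision model used to weigh that trade-off from the Chinese
healthcare-system perspective: a dynamic three-state cohort model
(progression free, PF; progressed disease, PD; death), parametric survival
extrapolation to a roughly lifetime horizon, drug costing with vial wastage
and a staged Patient Assistance Program (PAP), discounted life-years (LY),
quality-adjusted life-years (QALY) and incremental cost-effectiveness
ratios (ICER), plus one-way and probabilistic sensitivity analysis.

## State-transition structure

Three survival curves drive the model, all with time in months:

* **PFS** (progression-free survival) governs *all* exits from PF: the
  probability of leaving PF during a cycle $[t_0, t_1)$ is
  $1 - S_\mathrm{pfs}(t_1)/S_\mathrm{pfs}(t_0)$.
* **TTP** (time to progression) governs the PF $\to$ PD transition with the
  analogous conditional probability.
* **PPS** (post-progression survival) governs PD $\to$ death, evaluated on
  the *time-since-progression* clock.

The PF $\to$ death probability is the difference of the PFS and TTP cycle
probabilities, floored at zero. This split is the natural reading of a
model that derives its three transitions from exactly these three curves;
no published split rule exists, so the floor is a documented choice (the
floor only binds where independently fitted curves cross by fitting noise).

Because the PPS clock restarts at progression the model is semi-Markov: PD
occupancy is carried as *tunnel cohorts* indexed by entry time. A cohort
that entered PD at boundary $t_j$ contributes
$e_j\, S_\mathrm{pps}(t_m - t_j)$ to PD occupancy at boundary $t_m$, which
lets the engine evaluate the whole tunnel bookkeeping as one matrix
product rather than per-tunnel iteration. Elapsed time is carried in
months, so the change of cycle length at 12 months needs no re-binning. A
`pps_clock = "model_time"` switch exists to falsify the convention (the
log-normal PPS hazard decreases, so the model-time clock systematically
inflates PD person-time; the package default is the tunnel clock).

### Cycle grid

Following the dosing calendar, the first 12 months use 14-day cycles — 26
cycles, matching 26 two-weekly administrations (365.25 d / 14 d rounds to
26) — and 28-day cycles thereafter out to a 480-month (40-year) horizon.
Days convert at 30.4375 days/month. The default grid has 535 cycles.

### Accrual and discounting

Occupancy is valued at cycle start for the full cycle length; each cycle's
accrual is discounted at its midpoint by $(1+r)^{-t_\mathrm{mid}/12}$ with
$r = 5\%$/year for both costs and outcomes. QALYs weight PF and PD
person-time by utilities 0.901 and 0.863 (mixed-effect estimates from
EQ-5D-5L data). No half-cycle correction is applied by default; a
`half_cycle` switch averages start- and end-of-cycle occupancy instead
(its effect on the base case is below 1%). No general-population
background mortality is layered on the disease-specific curves, and no
cure fraction is assumed: the 40-year horizon truncates the extrapolated
tails.

## Survival curves and the generalized-gamma convention

Six families are supported (exponential, Weibull, log-normal,
log-logistic, Gompertz, generalized gamma), evaluated through the standard
distribution functions (`flexsurv` supplies the non-base families).
The generalized gamma uses the location/scale/signed-shape
parameterization $(\mu, \sigma, Q)$: for $Q < 0$,
$S(t) = P\!\left(\gamma,\, \gamma e^{Q w}\right)$ with $\gamma = Q^{-2}$,
$w = (\ln t - \mu)/\sigma$ and $P$ the regularized lower incomplete gamma
function.

The published curve parameters are printed as $(\beta, \sigma, k)$ with a
typeset survival formula whose shape sign is ambiguous. The package maps
$\mu = \beta$ and $Q = -k$ by default. This choice was fixed by clinical
scale, not by fitting: under $Q = -k$ with time in months the implied PFS
medians are 32.0 months (durvalumab) versus 6.4 months (BSC), matching
the trial's clinical direction (17.2 vs 5.6 months at interim follow-up),
and the log-normal PPS median $e^{3.0448} = 21.0$ months is plausible only
in months; under $Q = +k$ both arms collapse to sub-month medians. The raw
sign remains available as `conventions$gengamma_shape = "raw"` so the
acceptance harness can falsify the default.

### A reproducibility caveat, stated plainly

With these curves and this structure, the engine's discounted base-case
totals (durvalumab 8.63 LY / 7.72 QALY; BSC 5.07 LY / 4.48 QALY) exceed
the originally published totals (7.39/6.61 and 4.79/4.24) by 6–17% per
cell. The discrepancy is structural, not a convention choice: under the
negated-shape mapping 27% of the durvalumab cohort is still progression
free at 40 years, while the original analysis states that the whole cohort
has died by its horizon. Sweeping every documented switch (shape sign,
half-cycle correction, PPS clock) moves the totals by under 1%, a single
effective discount rate cannot reconcile both arms simultaneously, and a
fitted two-parameter background-mortality overlay still leaves 5%+ cell
errors with an implausibly flat hazard. The published totals therefore
appear to involve an additional, undisclosed mortality or tail-truncation
mechanism. The package implements the structure as described and reports
its own computed values; the acceptance test records the gap rather than
absorbing it.

## Fitting machinery

`fit_parametric()` maximizes the right-censored log-likelihood
$\sum_i \left[\delta_i \ln f(t_i) + (1-\delta_i)\ln S(t_i)\right]$
via `flexsurv::flexsurvreg` (quasi-Newton on log-transformed positive
parameters), wrapped in a deterministic multi-start (default inits plus
four fixed perturbation factors; best converged optimum kept). AIC
($2p - 2\ell$) and BIC ($p\ln n - 2\ell$) are recomputed from the
likelihood; `select_best()` minimizes the chosen criterion with
deterministic tie-breaks (fewer parameters, then family enumeration
order). Standard errors are delta-method values on the natural parameter
scale. Non-convergence of every start is an explicit error, never a
silent partial fit.

## Costing

Drug acquisition uses exact vial arithmetic: the cheapest combination of
120 mg (¥6,066) and 500 mg (¥18,088) vials covering the 612 mg dose
(10 mg/kg × 61.2 kg) is one of each, ¥24,154 per administration, found by
bounded exhaustive search with wastage paid. Retail dosing runs 26
administrations (¥628,004 payable maximum); under the PAP the patient pays
administrations 1–2 and 5–8 only (¥144,924 maximum), with "cycle" read as
one two-weekly administration. Drug cost applies to the PF fraction only
(treatment stops at progression and at 12 months).

Recurring medical-resource costs are monthly rates multiplied by state
occupancy and cycle length — monthly rates rather than per-cycle amounts
so the 14-day/28-day phase change cannot silently halve a cost. Terminal
care is a one-off applied to incident deaths; adverse-event treatment is
an incidence-weighted one-off at entry. The original unit prices for
drugs and radiotherapy are carried with their PSA distributions, but the
resource-use quantities behind medical service, inspections, subsequent
treatment and adverse events were collected by expert survey and never
published: the shipped values (¥800/month PF, ¥1,200/month PD, ¥20,000
terminal, a four-regimen subsequent mix with illustrative monthly unit
consumption) are **placeholders**, flagged as such in every run manifest.
Absolute cost totals and ICERs from the shipped configuration are
therefore illustrative only; the engine reproduces the published cost
accounting once real resource-use inputs are supplied.

## Comparative synthesis and sensitivity analysis

`compare_arms()` reports incremental cost, QALYs and LYs, the ICER (with
dominance labels and an explicit undefined state at zero incremental
QALYs), net monetary benefit, and the decision at the willingness-to-pay
threshold of ¥212,676/QALY (three times 2019 GDP per capita; configurable).

One-way sensitivity analysis moves each parameter to its 95% bounds
(printed ranges where available, else $\pm 1.96\,\mathrm{SE}$) and sorts by
ICER swing. The PSA samples gamma parameters by moment matching
(shape $=(\mu/\mathrm{SE})^2$), betas by moment matching on mean and SE,
normals and uniforms directly; parameters are drawn independently (no
correlation structure was published) and survival curves are held fixed —
no sampling law for their uncertainty was published either, and the run
log flags this. The PSA ICER follows the ratio-of-means convention, and
the CEAC grid spans ¥0–400,000 in ¥2,000 steps, covering the threshold
and the published crossover region. Because curves are fixed, occupancy
traces are computed once and reused across draws, so a 1,000-draw PSA
takes seconds.

## Synthetic patient-level data

The trial's patient-level data are not public, so the generator emulates
the structure the analysis assumes: progression times from the TTP curve;
pre-progression deaths with hazard
$\max(0,\, h_\mathrm{pfs} - h_\mathrm{ttp})$, drawn by inverting the
cumulative excess hazard on a dense grid (4,000 points; exact in law and
deterministic in cost, which is why inversion was preferred over
thinning — the gengamma families provide no cheap hazard majorant);
post-progression survival from the PPS curve for progressors;
administrative right-censoring. Utility observations follow a two-level
model: state mean + patient intercept $\sim N(0, \sigma_b)$ + residual
$\sim N(0, \sigma_e)$, clamped to the instrument range $[-0.5, 1]$,
assessed every 1.5 months (approximately the trial's schedule) until death
or censoring. Defaults $\sigma_b = \sigma_e = 0.05$ give utility spreads
typical of EQ-5D data in this population. `estimate_state_utilities()`
recovers the state means with a patient random-intercept model (`lme4`),
falling back to exact means on degenerate zero-noise input.

What the generator does *not* emulate: informative censoring, utility
drift with time-to-death, covariate effects, measurement floor/ceiling
clustering, or the original trial's exact follow-up pattern. Passing
recovery tests therefore demonstrate correctness of the fitting and
estimation machinery under the assumed data-generating process, not
robustness to real-data violations of it.

Independently fitted TTP and PFS curves can cross by fitting noise (the
shipped curves do, by $1.4\times10^{-4}$ in survival around 1.2–1.4
months). The generator tolerates excursions up to $10^{-3}$ — flooring
the excess hazard to zero there, exactly as the engine does — and rejects
larger violations as genuinely inconsistent inputs, naming the offending
time.

## Numerical choices

* Medians by closed form (exponential, log-normal) or bracketed
  root-finding to $10^{-8}$ relative tolerance, with an explicit
  "not reached" result on $(0, 10^6]$ months.
* Occupancy conservation is asserted to $10^{-10}$ every cycle; negative
  occupancy aborts the run rather than being clamped.
* Survival ratios at extinct states return transition probability 1 with a
  warning.
* The gengamma $Q \to 0$ limit approaches the log-normal linearly in $Q$
  (deviation $\approx 1.3\times10^{-4}$ at $|Q| = 10^{-3}$ for the PPS
  parameters); the suite asserts the linear convergence rate.
* Exact AIC ties break to fewer parameters, then family order.

## Problem sizes used by the test suite

The suite exercises: parameter recovery for all six families at $n=2{,}000$
with ~30% administrative censoring; an independent 100,000-walker
microsimulation oracle against the cohort engine on five randomized
configurations (240-month grid); Kaplan–Meier agreement of simulated PFS
at $n=5{,}000$; utility recovery at 2,000 patients; sampler moment
recovery at $n=10^5$; and a full 1,000-draw PSA. The complete suite runs
in about half a minute on one core.

## Known limitations

* The published base-case LY/QALY totals are not reproducible from the
  published inputs alone (see the caveat above); the package reports its
  own faithfully computed values and documents the gap.
* Resource-use quantities are placeholders pending real-world inputs.
* No spline or flexible-hazard extrapolation, covariate-adjusted survival,
  interval censoring, treatment waning, or multi-way (>2 arm) frontiers.
* The individual-level microsimulation exists only as a test oracle, not
  a user-facing mode.
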