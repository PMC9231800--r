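exp_arm <- function(lam_ttp, lam_pfs, lam_pps, u_pf = 1, u_pd = 1) {
  arm_spec("toy",
           ttp = surv_curve("exponential", lam_ttp),
           pfs = surv_curve("exponential", lam_pfs),
           pps = surv_curve("exponential", lam_pps),
           utility_pf = u_pf, utility_pd = u_pd)
}

test_that("cycle grid has 26 fourteen-day cycles then 28-day cycles to the horizon", {
  g <- build_cycle_grid()
  expect_equal(g$boundaries[1], 0)
  expect_equal(g$boundaries[2], 14 / 30.4375)
  expect_equal(g$n_first_phase, 26)
  expect_true(all(abs(diff(g$boundaries[1:27]) - 14 / 30.4375) < 1e-12))
  expect_true(all(abs(diff(g$boundaries[-(1:27)]) - 28 / 30.4375) < 1e-12))
  expect_gte(max(g$boundaries), 480)
  expect_error(build_cycle_grid(horizon_months = 6), "must exceed")
  expect_error(build_cycle_grid(first_cycle_days = -1), "positive")
})

test_that("occupancies conserve mass, dead is monotone, PF never gains", {
  g <- build_cycle_grid()
  arms <- c(table1_arms(), list(toy = exp_arm(0.05, 0.06, 0.1)))
  for (arm in arms) {
    tr <- run_cohort(arm, g)$trace
    expect_true(all(abs(tr$pf + tr$pd + tr$dead - 1) < 1e-10))
    expect_true(all(tr$pf >= 0 & tr$pd >= 0 & tr$dead >= 0))
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_true(all(diff(tr$pf) <= 1e-12))
    expect_true(all(tr$incident_deaths >= -1e-12))
  }
})

test_that("unit utilities make QALYs equal life-years exactly", {
  g <- build_cycle_grid()
  e <- run_cohort(exp_arm(0.04, 0.05, 0.08), g, discount = 0.05)$econ
  expect_equal(e$qaly_total, e$ly_total)
  expect_equal(e$qaly_total_undisc, e$ly_total_undisc)
  # proportional weighting by state utility
  arm <- exp_arm(0.04, 0.05, 0.08, u_pf = 0.9, u_pd = 0.7)
  e2 <- run_cohort(arm, g, discount = 0.05)$econ
  expect_equal(e2$qaly_pf, 0.9 * e2$ly_pf)
  expect_equal(e2$qaly_pd, 0.7 * e2$ly_pd)
  expect_equal(e2$qaly_total, e2$qaly_pf + e2$qaly_pd)
})

test_that("totals strictly decrease in the discount rate", {
  g <- build_cycle_grid()
  arm <- table1_arms()$durvalumab
  rates <- c(0, 0.03, 0.05, 0.08)
  ly <- vapply(rates, function(r) run_cohort(arm, g, r)$econ$ly_total,
               numeric(1))
  q <- vapply(rates, function(r) run_cohort(arm, g, r)$econ$qaly_total,
              numeric(1))
  expect_true(all(diff(ly) < 0))
  expect_true(all(diff(q) < 0))
  expect_equal(ly[1], run_cohort(arm, g, 0)$econ$ly_total_undisc)
})

test_that("pointwise-dominating PFS and TTP curves give no fewer life-years", {
  g <- build_cycle_grid()
  pps <- surv_curve("lognormal", c(3.0448, 1.1876))
  a <- arm_spec("a", surv_curve("exponential", 0.04),
                surv_curve("exponential", 0.05), pps)
  b <- arm_spec("b", surv_curve("exponential", 0.06),
                surv_curve("exponential", 0.08), pps)
  expect_gte(run_cohort(a, g, 0)$econ$ly_total_undisc,
             run_cohort(b, g, 0)$econ$ly_total_undisc)
})

test_that("exponential PF person-time approaches 1/lambda over a long horizon", {
  g <- build_cycle_grid()
  lam <- 0.1   # S(480) = e^-48: truncation far below 1e-6
  e <- run_cohort(exp_arm(lam, lam, 1), g, discount = 0)$econ
  # occupancy-at-cycle-start accrual overestimates the integral by at most
  # one cycle's worth of the per-cycle decrement; compare against the exact
  # discrete sum rather than a loose band
  b <- g$boundaries
  exact <- sum(exp(-lam * b[-length(b)]) * diff(b)) / 12
  expect_equal(e$ly_pf, exact, tolerance = 1e-10)
  expect_equal(12 * e$ly_pf, 1 / lam, tolerance = 0.05)
})

test_that("cohort engine agrees with the individual-level microsimulation", {
  g <- build_cycle_grid(horizon_months = 240)
  arm <- exp_arm(0.05, 0.06, 0.09)
  eng <- run_cohort(arm, g, discount = 0)$econ$ly_total_undisc
  ms <- microsim_ly(arm, g, n = 1e5, seed = 5)
  expect_lt(abs(eng - ms$mean), 3 * ms$se)
})

test_that("PPS clock convention changes post-progression survival as expected", {
  g <- build_cycle_grid()
  arm <- table1_arms()$bsc
  tun <- run_cohort(arm, g, pps_clock = "since_progression")$econ
  mod <- run_cohort(arm, g, pps_clock = "model_time")$econ
  # lognormal PPS hazard falls with time, so the model-time clock gives
  # later entrants a lower death hazard and more PD person-time
  expect_gt(mod$ly_pd_undisc, tun$ly_pd_undisc)
  expect_equal(mod$ly_pf_undisc, tun$ly_pf_undisc)
})

test_that("half-cycle correction shrinks PF accrual by at most one cycle", {
  g <- build_cycle_grid()
  arm <- table1_arms()$durvalumab
  full <- run_cohort(arm, g, half_cycle = FALSE)$econ
  half <- run_cohort(arm, g, half_cycle = TRUE)$econ
  expect_lt(half$ly_pf, full$ly_pf)
  expect_lt(full$ly_pf - half$ly_pf, max(g$lengths) / 12)
})

test_that("trace CSV round-trips losslessly", {
  g <- build_cycle_grid(horizon_months = 24)
  tr <- run_cohort(exp_arm(0.1, 0.12, 0.2), g)$trace
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_equal(nrow(tr2), nrow(tr))
  for (col in c("t_start", "t_end", "pf", "pd", "dead",
                "incident_progressions", "incident_deaths"))
    expect_equal(tr2[[col]], tr[[col]], tolerance = 1e-12)
  expect_true(all(abs(tr2$pf + tr2$pd + tr2$dead - 1) < 1e-10))
})

test_that("tunnel occupancy matrix is kept on request and sums to the PD column", {
  g <- build_cycle_grid(horizon_months = 36)
  out <- run_cohort(table1_arms()$bsc, g, keep_tunnel = TRUE)
  tun <- attr(out$trace, "pd_tunnel")
  expect_equal(dim(tun), c(g$n_cycles, g$n_cycles))
  expect_equal(rowSums(tun), out$trace$pd, tolerance = 1e-12)
})
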