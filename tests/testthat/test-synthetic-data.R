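toy_arms <- function() {
  list(durvalumab = list(ttp = surv_curve("exponential", 0.04),
                         pfs = surv_curve("exponential", 0.05),
                         pps = surv_curve("lognormal", c(3.0448, 1.1876))),
       bsc = list(ttp = surv_curve("exponential", 0.10),
                  pfs = surv_curve("exponential", 0.12),
                  pps = surv_curve("lognormal", c(3.0448, 1.1876))))
}

test_that("the generator is deterministic under a seed and censors at the boundary", {
  cfg <- sim_config(n_per_arm = 50, arms = toy_arms(), seed = 5)
  expect_identical(simulate_ipd(cfg), simulate_ipd(cfg))
  cfg2 <- sim_config(n_per_arm = 50, arms = toy_arms(), seed = 6)
  expect_false(identical(simulate_ipd(cfg), simulate_ipd(cfg2)))
  # near-zero administrative censoring time censors essentially everyone
  tiny <- sim_config(n_per_arm = 200, arms = toy_arms(),
                     censor_time = 0.001, seed = 7)
  ipd <- simulate_ipd(tiny)
  expect_lt(mean(ipd$durvalumab$pfs$event), 0.01)
  expect_true(all(ipd$durvalumab$pfs$time <= 0.001))
})

test_that("inconsistent curves (PFS above TTP) are rejected with the offending time", {
  bad <- list(arm = list(ttp = surv_curve("exponential", 0.2),
                         pfs = surv_curve("exponential", 0.1),
                         pps = surv_curve("exponential", 0.1)))
  cfg <- sim_config(n_per_arm = 20, arms = bad, seed = 1)
  expect_error(simulate_ipd(cfg), "S_pfs > S_ttp at t")
})

test_that("simulated PFS exit times reproduce the generating survival curve", {
  cfg <- sim_config(n_per_arm = 5000, arms = toy_arms()["durvalumab"],
                    censor_time = 1e6, seed = 11)
  ipd <- simulate_ipd(cfg)
  pfs <- ipd$durvalumab$pfs
  expect_true(all(pfs$event == 1))
  km <- survival::survfit(survival::Surv(time, event) ~ 1, data = pfs)
  truth <- surv_prob(toy_arms()$durvalumab$pfs, km$time)
  expect_lt(max(abs(km$surv - truth)), 0.03)
})

test_that("utility observations have the specified state means and clustering", {
  # zero noise: every observation equals the state mean exactly
  cfg0 <- sim_config(n_per_arm = 30, arms = toy_arms(), sd_between = 0,
                     sd_resid = 0, seed = 21)
  obs0 <- simulate_utilities(cfg0, simulate_ipd(cfg0))
  expect_true(all(obs0$value[obs0$state == "PF"] == 0.901))
  expect_true(all(obs0$value[obs0$state == "PD"] == 0.863))
  expect_true(all(obs0$value >= -0.5 & obs0$value <= 1))
  est0 <- estimate_state_utilities(obs0)
  expect_equal(est0$mean_pf, 0.901)
  expect_equal(est0$mean_pd, 0.863)
  expect_equal(est0$se_pf, 0)
  # a patient who never progresses contributes no PD rows
  ipd0 <- simulate_ipd(cfg0)
  p <- ipd0$durvalumab$patients
  never <- p$id[p$t_prog >= pmin(p$t_death_pre, p$censor_time)]
  expect_false(any(obs0$patient %in% never & obs0$state == "PD"))
})

test_that("the clustered estimator recovers noisy state means within 3 SE", {
  cfg <- sim_config(n_per_arm = 1000, arms = toy_arms(), sd_between = 0.05,
                    sd_resid = 0.05, seed = 33)
  obs <- simulate_utilities(cfg, simulate_ipd(cfg))
  expect_gt(length(unique(obs$patient)), 500)
  est <- estimate_state_utilities(obs)
  expect_identical(est$method, "random-intercept (lmer)")
  expect_lt(abs(est$mean_pf - 0.901), 3 * est$se_pf)
  expect_lt(abs(est$mean_pd - 0.863), 3 * est$se_pd)
  # consistency: bias shrinks with n (checked against a small-n fit)
  cfg_small <- sim_config(n_per_arm = 100, arms = toy_arms(),
                          sd_between = 0.05, sd_resid = 0.05, seed = 34)
  obs_small <- simulate_utilities(cfg_small, simulate_ipd(cfg_small))
  est_small <- estimate_state_utilities(obs_small)
  expect_lt(est$se_pf, est_small$se_pf)
})

test_that("estimator handles toy, permuted, and single-state inputs", {
  toy <- data.frame(
    patient = c("a", "a", "b", "b"),
    time = c(0, 1, 0, 1),
    state = c("PF", "PD", "PF", "PD"),
    value = c(0.92, 0.88, 0.90, 0.84))
  est <- estimate_state_utilities(toy)
  # balanced design: the clustered estimator equals the plain state means
  expect_equal(est$mean_pf, mean(c(0.92, 0.90)), tolerance = 1e-6)
  expect_equal(est$mean_pd, mean(c(0.88, 0.84)), tolerance = 1e-6)
  # invariance to patient relabelling
  perm <- toy[c(3, 4, 1, 2), ]
  perm$patient <- c("x", "x", "y", "y")
  est_perm <- estimate_state_utilities(perm)
  expect_equal(est_perm$mean_pf, est$mean_pf, tolerance = 1e-9)
  expect_equal(est_perm$mean_pd, est$mean_pd, tolerance = 1e-9)
  # a state with no observations is reported inestimable, not invented
  pf_only <- toy[toy$state == "PF", ]
  est_pf <- estimate_state_utilities(pf_only)
  expect_identical(est_pf$inestimable, "PD")
  expect_true(is.na(est_pf$mean_pd))
  expect_equal(est_pf$mean_pf, 0.91)
  expect_error(estimate_state_utilities(toy[1:2, ]), "at least 2 patients")
})

test_that("end-to-end: fit on synthetic data reproduces the true-curve pipeline within 5%", {
  cfg <- default_config()
  grid <- do.call(build_cycle_grid, cfg$grid)
  arms_true <- table1_arms()
  sim <- sim_config(n_per_arm = 2000, arms = lapply(arms_true, function(a)
    list(ttp = a$ttp, pfs = a$pfs, pps = a$pps)),
    censor_time = 120, seed = 91)
  ipd <- simulate_ipd(sim)
  for (an in names(arms_true)) {
    fitted <- arm_spec(
      an,
      ttp = fit_parametric(ipd[[an]]$ttp, "gengamma")$curve,
      pfs = fit_parametric(ipd[[an]]$pfs, "gengamma")$curve,
      pps = fit_parametric(ipd[[an]]$pps, "lognormal")$curve)
    e_true <- run_cohort(arms_true[[an]], grid, discount = 0.05)$econ
    e_fit <- run_cohort(fitted, grid, discount = 0.05)$econ
    expect_lt(abs(e_fit$ly_total / e_true$ly_total - 1), 0.05)
    expect_lt(abs(e_fit$qaly_total / e_true$qaly_total - 1), 0.05)
  }
})
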