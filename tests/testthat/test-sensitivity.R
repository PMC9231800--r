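toy_specs <- rbind(
  param_spec("utility_pf", 0.901, 0.009, 0.883, 0.918, "beta"),
  param_spec("utility_pd", 0.863, 0.009, 0.845, 0.880, "beta"),
  param_spec("discount", 0.05, NA, 0, 0.08, "uniform"),
  param_spec("price_durvalumab_120", 6066, 606.6, 4935.54, 7311.29, "gamma"),
  param_spec("weight", 61.2, 0.74, NA, NA, "fixed"))

test_that("parameter samplers are seeded, degenerate at SE = 0, and validated", {
  d1 <- sample_params(toy_specs, 50, seed = 123)
  d2 <- sample_params(toy_specs, 50, seed = 123)
  expect_identical(d1, d2)
  expect_false(identical(d1, sample_params(toy_specs, 50, seed = 124)))
  expect_true(all(d1$weight == 61.2))
  zero <- param_spec("x", 10, 0, dist = "gamma")
  expect_true(all(sample_params(zero, 20, seed = 1)$x == 10))
  # beta moment matching infeasible when SE too large for the mean
  bad <- param_spec("u", 0.5, 0.6, dist = "beta")
  expect_error(sample_params(bad, 10, seed = 1), "infeasible.*'u'")
  expect_error(param_spec("y", 5, low = 6, high = 7, dist = "uniform"),
               "low <= base <= high")
})

test_that("samplers recover their specified moments", {
  n <- 1e5
  specs <- rbind(
    param_spec("g", 6066, 606.6, dist = "gamma"),
    param_spec("b", 0.901, 0.009, dist = "beta"),
    param_spec("n", 62.9, 0.34, dist = "normal"),
    param_spec("u", 0, NA, 0, 8, dist = "uniform"))
  d <- sample_params(specs, n, seed = 99)
  check_mom <- function(x, mean_true, sd_true) {
    expect_lt(abs(mean(x) - mean_true), 3 * sd_true / sqrt(n))
    expect_lt(abs(sd(x) - sd_true), 3 * sd_true / sqrt(2 * n))
  }
  check_mom(d$g, 6066, 606.6)
  check_mom(d$b, 0.901, 0.009)
  check_mom(d$n, 62.9, 0.34)
  check_mom(d$u, 4, 8 / sqrt(12))
})

test_that("OWSA orders by swing, keeps fixed parameters at zero swing, flags failures", {
  # analytic toy model: ICER = (c0 + a*price - 0) / dq(u)
  runner <- function(ov) {
    p <- c(price = 100, u = 0.5)
    p[names(ov)] <- ov
    dq <- p[["u"]] - 0.3
    dc <- 1000 + 10 * p[["price"]]
    icer <- if (dq > 0) dc / dq else NA_real_
    list(icer = icer, delta_cost = dc, delta_qaly = dq,
         label = if (dq > 0) "ICER" else "dominated")
  }
  specs <- rbind(
    param_spec("price", 100, 10, 80.4, 119.6, "gamma"),
    param_spec("u", 0.5, 0.05, 0.4, 0.6, "beta"),
    param_spec("fixed_par", 7, 0, 7, 7, "fixed"))
  tor <- run_owsa(runner, specs)
  expect_equal(nrow(tor), 3)
  expect_true(all(diff(ifelse(is.na(tor$swing), -Inf, tor$swing)) <= 0))
  expect_equal(tor$swing[tor$parameter == "fixed_par"], 0)
  expect_equal(tor$parameter[3], "fixed_par")   # zero swing sorts last
  # pure-cost parameter: ICER shift equals d(delta cost)/dQALY, two ways
  shift_owsa <- with(tor[tor$parameter == "price", ],
                     icer_high - icer_low)
  shift_direct <- 10 * (119.6 - 80.4) / (0.5 - 0.3)
  expect_equal(shift_owsa, shift_direct, tolerance = 1e-9)
  # perturbation driving dQALY <= 0 is flagged, not dropped
  specs2 <- rbind(specs,
                  param_spec("u_bad", 0.5, NA, 0.1, 0.9, "uniform"))
  runner2 <- function(ov) {
    names(ov)[names(ov) == "u_bad"] <- "u"
    runner(ov)
  }
  tor2 <- run_owsa(runner2, specs2)
  expect_match(tor2$note[tor2$parameter == "u_bad"], "dominated")
})

test_that("all-fixed PSA reproduces the base case bit-identically", {
  cfg <- default_config()
  runner <- make_model_runner(cfg)
  base <- runner()
  specs <- cfg$params
  specs$dist <- "fixed"
  psa <- run_psa(runner, specs, n = 8, seed = 77, wtp = cfg$wtp)
  expect_identical(unique(psa$samples$delta_cost), base$delta_cost)
  expect_identical(unique(psa$samples$delta_qaly), base$delta_qaly)
  expect_true(psa$summary$prob_ce %in% c(0, 1))
})

test_that("CEAC endpoint identities and the single-atom step function hold", {
  samples <- data.frame(delta_cost = c(-5, 10, 20, -1),
                        delta_qaly = c(1, 2, -0.5, -0.2))
  cc <- ceac(samples, wtp_grid = c(0, 1e9))
  expect_equal(cc$probability[1], mean(samples$delta_cost < 0))
  expect_equal(cc$probability[2], mean(samples$delta_qaly > 0))
  expect_equal(cc$probability[1] + mean(samples$delta_cost >= 0), 1)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  atom <- data.frame(delta_cost = rep(100, 4), delta_qaly = rep(2, 4))
  step <- ceac(atom, wtp_grid = c(49, 49.999, 50.001, 60))
  expect_equal(step$probability, c(0, 0, 1, 1))
  expect_error(ceac(samples, numeric(0)), "empty")
  expect_error(ceac(samples, -1), "non-negative")
})

test_that("utilities-only PSA keeps mean incremental QALYs near the base case", {
  cfg <- default_config()
  runner <- make_model_runner(cfg)
  base <- runner()
  specs <- cfg$params
  specs$dist[!specs$name %in% c("utility_pf", "utility_pd")] <- "fixed"
  psa <- run_psa(runner, specs, n = 200, seed = 31, wtp = cfg$wtp)
  emp_se <- sd(psa$samples$delta_qaly) / sqrt(nrow(psa$samples))
  expect_lt(abs(psa$summary$mean_delta_qaly - base$delta_qaly), 3 * emp_se)
  # costs fixed: every draw has the base-case incremental cost
  expect_equal(unique(psa$samples$delta_cost), base$delta_cost)
})
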