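# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: brute-force enumeration for the vial optimizer, an
# individual-level microsimulation for the cohort engine, quadrature for
# survival functions.

# exhaustive vial enumeration over the full count grid (no pruning)
brute_force_vial_cost <- function(dose_mg, sizes, prices) {
  grids <- lapply(sizes, function(s) 0:ceiling(dose_mg / s))
  combos <- as.matrix(expand.grid(grids))
  covered <- combos %*% sizes >= dose_mg
  min((combos %*% prices)[covered])
}

# individual-level microsimulation with the engine's per-cycle update rules:
# categorical exit-cycle draw from the same cycle probabilities, exit-type
# split, tunnel PPS death draw; accrual values occupancy at cycle start.
microsim_ly <- function(arm, grid, n = 1e5, seed = 1) {
  set.seed(seed)
  b <- grid$boundaries
  nc <- grid$n_cycles
  s_pfs <- surv_prob(arm$pfs, b)
  s_ttp <- surv_prob(arm$ttp, b)
  p_leave <- ifelse(s_pfs[-(nc + 1)] > 0, 1 - s_pfs[-1] / s_pfs[-(nc + 1)], 1)
  p_prog <- ifelse(s_ttp[-(nc + 1)] > 0, 1 - s_ttp[-1] / s_ttp[-(nc + 1)], 1)
  p_pfd <- pmax(0, p_leave - p_prog)
  q <- pmin(p_prog + p_pfd, 1)
  surv_before <- cumprod(c(1, 1 - q))[1:nc]
  pmf_exit <- surv_before * q
  cdf <- cumsum(pmf_exit)
  u <- runif(n)
  exit_cycle <- findInterval(u, cdf) + 1L   # nc + 1 means: still in PF at horizon
  in_pf_to_end <- exit_cycle > nc
  pf_time <- ifelse(in_pf_to_end, b[nc + 1], b[pmin(exit_cycle, nc) + 1])
  is_prog <- rep(FALSE, n)
  idx <- which(!in_pf_to_end)
  if (length(idx)) {
    pp <- p_prog[exit_cycle[idx]] / q[exit_cycle[idx]]
    is_prog[idx] <- runif(length(idx)) < pp
  }
  pd_time <- numeric(n)
  for (ec in sort(unique(exit_cycle[is_prog]))) {
    w <- which(is_prog & exit_cycle == ec)
    entry <- b[ec + 1]
    offs <- b[(ec + 1):(nc + 1)] - entry
    pmf <- -diff(surv_prob(arm$pps, offs))
    len <- length(pmf)
    if (len == 0) next
    dc <- findInterval(runif(length(w)), cumsum(pmf)) + 1L
    pd_time[w] <- ifelse(dc > len, b[nc + 1] - entry, offs[pmin(dc, len) + 1])
  }
  per_walker <- (pf_time + pd_time) / 12
  list(mean = mean(per_walker), se = sd(per_walker) / sqrt(n))
}

# quadrature survival check: S(t) = exp(-integral of hazard)
surv_from_hazard <- function(curve, t) {
  H <- stats::integrate(function(u) surv_hazard(curve, u), 1e-10, t,
                        rel.tol = 1e-10)$value
  exp(-H)
}

table1_arms <- function() {
  cfg <- default_config()
  list(durvalumab = build_arm(cfg, "durvalumab"),
       bsc = build_arm(cfg, "bsc"))
}

# minimal fabricated arm results for comparison-layer unit tests
fake_arm_result <- function(cost, qaly, ly = qaly, discount = 0.05) {
  list(econ = structure(list(qaly_total = qaly, ly_total = ly,
                             discount_rate = discount),
                        class = "econ_result"),
       cost = structure(list(total = cost), class = "cost_result"))
}
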