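#' Build the model's cycle grid
#'
#' The base-case grid follows the trial's dosing calendar: 14-day cycles for
#' the first 12 months (26 cycles, matching 26 q2w administrations), then
#' 28-day cycles out to the 40-year horizon. Boundaries are returned in
#' months (days convert at 30.4375 days/month).
#'
#' @param first_cycle_days Cycle length in the first phase (days).
#' @param later_cycle_days Cycle length after the phase switch (days).
#' @param phase_switch_months Duration of the first phase (months).
#' @param horizon_months Model horizon (months).
#' @return An object of class `cycle_grid` with elements `boundaries`
#'   (months, starting at 0), `lengths`, `midpoints`, `n_cycles`,
#'   `n_first_phase`, and the construction settings.
#' @export
build_cycle_grid <- function(first_cycle_days = 14, later_cycle_days = 28,
                             phase_switch_months = 12, horizon_months = 480) {
  if (first_cycle_days <= 0 || later_cycle_days <= 0)
    stop("cycle lengths must be positive")
  if (horizon_months <= phase_switch_months)
    stop("horizon must exceed the phase switch")
  n1 <- round(phase_switch_months * DAYS_PER_MONTH / first_cycle_days)
  if (n1 < 1) stop("first phase shorter than one cycle")
  d1 <- first_cycle_days / DAYS_PER_MONTH
  d2 <- later_cycle_days / DAYS_PER_MONTH
  b1 <- (0:n1) * d1
  n2 <- ceiling((horizon_months - b1[n1 + 1]) / d2)
  boundaries <- c(b1, b1[n1 + 1] + seq_len(n2) * d2)
  lengths <- diff(boundaries)
  structure(list(boundaries = boundaries, lengths = lengths,
                 midpoints = boundaries[-length(boundaries)] + lengths / 2,
                 n_cycles = length(lengths), n_first_phase = n1,
                 first_cycle_days = first_cycle_days,
                 later_cycle_days = later_cycle_days,
                 phase_switch_months = phase_switch_months,
                 horizon_months = horizon_months),
            class = "cycle_grid")
}

#' @export
print.cycle_grid <- function(x, ...) {
  cat(sprintf(paste0("<cycle_grid> %d cycles: %d x %g d then %d x %g d, ",
                     "horizon %.1f months\n"),
              x$n_cycles, x$n_first_phase, x$first_cycle_days,
              x$n_cycles - x$n_first_phase, x$later_cycle_days,
              max(x$boundaries)))
  invisible(x)
}

#' Specify a comparator arm
#'
#' Bundles the three survival curves governing the arm's transitions with its
#' state utilities. PFS governs all exits from the progression-free (PF)
#' state, TTP the PF-to-progressed-disease (PD) transition, and PPS the
#' PD-to-death transition on the time-since-progression clock.
#'
#' @param name Arm label.
#' @param ttp,pfs,pps [surv_curve()] objects.
#' @param utility_pf,utility_pd State utilities in `[0, 1]`. A draw with
#'   `utility_pd > utility_pf` warns rather than fails (probabilistic
#'   sensitivity analysis may produce such draws).
#' @return Object of class `arm_spec`.
#' @export
arm_spec <- function(name, ttp, pfs, pps,
                     utility_pf = 0.901, utility_pd = 0.863) {
  for (cv in list(ttp, pfs, pps)) .check_curve(cv)
  if (any(c(utility_pf, utility_pd) < 0 | c(utility_pf, utility_pd) > 1))
    stop("utilities must lie in [0, 1]")
  if (utility_pd > utility_pf)
    warning("utility_pd exceeds utility_pf")
  structure(list(name = name, ttp = ttp, pfs = pfs, pps = pps,
                 utility_pf = utility_pf, utility_pd = utility_pd),
            class = "arm_spec")
}

# State-occupancy trace on a grid. PF evolves by the per-cycle PFS exit
# probability split into progression (TTP) and a non-progression death
# remainder floored at 0; PD is carried as tunnel cohorts indexed by entry
# boundary so the PPS clock can restart at progression.
.compute_trace <- function(arm, grid,
                           pps_clock = c("since_progression", "model_time")) {
  pps_clock <- match.arg(pps_clock)
  b <- grid$boundaries
  n <- grid$n_cycles
  s_pfs <- surv_prob(arm$pfs, b)
  s_ttp <- surv_prob(arm$ttp, b)
  p_leave <- ifelse(s_pfs[-(n + 1)] > 0, 1 - s_pfs[-1] / s_pfs[-(n + 1)], 1)
  p_prog  <- ifelse(s_ttp[-(n + 1)] > 0, 1 - s_ttp[-1] / s_ttp[-(n + 1)], 1)
  p_pf_death <- pmax(0, p_leave - p_prog)
  p_exit <- pmin(p_prog + p_pf_death, 1)

  pf <- numeric(n + 1)  # occupancy at boundaries
  pf[1] <- 1
  for (i in seq_len(n)) pf[i + 1] <- pf[i] * (1 - p_exit[i])
  prog   <- pf[1:n] * p_prog        # entrants to PD at boundary i + 1
  pf_die <- pf[1:n] * p_pf_death

  entry <- b[-1]                    # entry times of tunnel cohorts
  if (pps_clock == "since_progression") {
    # pd occupancy at boundary m: sum over cohorts entered at or before b[m]
    off <- outer(b, entry, "-")
    keep <- off >= -1e-12
    surv <- matrix(0, n + 1, n)
    surv[keep] <- surv_prob(arm$pps, pmax(off[keep], 0))
    pd_b <- as.numeric(surv %*% prog)
  } else {
    s_pps <- surv_prob(arm$pps, b)
    ratio <- ifelse(s_pps[-(n + 1)] > 0, s_pps[-1] / s_pps[-(n + 1)], 0)
    pd_b <- numeric(n + 1)
    for (i in seq_len(n)) pd_b[i + 1] <- pd_b[i] * ratio[i] + prog[i]
  }
  pd_die <- pd_b[1:n] + prog - pd_b[-1]
  dead <- c(0, cumsum(pf_die + pd_die))

  resid <- abs(pf + pd_b + dead - 1)
  if (max(resid) > 1e-10)
    stop(sprintf("internal consistency failure: occupancy residual %.3e",
                 max(resid)))
  if (min(pf, pd_b, dead, pf_die, pd_die) < -1e-12)
    stop("internal consistency failure: negative occupancy")

  list(pf = pf, pd = pd_b, dead = dead, entrants = prog,
       pf_deaths = pf_die, pd_deaths = pd_die, pps_clock = pps_clock)
}

# Discounted and undiscounted accrual from precomputed occupancy vectors.
# Accrual values occupancy at cycle start for the full cycle length (or the
# start/end average under the half-cycle correction); discounting applies the
# annual rate at the cycle midpoint.
.accrue_econ <- function(state, grid, discount, utility_pf, utility_pd,
                         half_cycle = FALSE) {
  n <- grid$n_cycles
  dl_y <- grid$lengths / 12
  w <- (1 + discount)^(-grid$midpoints / 12)
  occ_pf <- state$pf[1:n]
  occ_pd <- state$pd[1:n]
  if (half_cycle) {
    occ_pf <- (occ_pf + state$pf[-1]) / 2
    occ_pd <- (occ_pd + state$pd[-1]) / 2
  }
  ly <- function(occ, wt) sum(occ * dl_y * wt)
  res <- list(
    ly_pf = ly(occ_pf, w), ly_pd = ly(occ_pd, w),
    ly_pf_undisc = ly(occ_pf, 1), ly_pd_undisc = ly(occ_pd, 1))
  res$ly_total <- res$ly_pf + res$ly_pd
  res$ly_total_undisc <- res$ly_pf_undisc + res$ly_pd_undisc
  res$qaly_pf <- res$ly_pf * utility_pf
  res$qaly_pd <- res$ly_pd * utility_pd
  res$qaly_total <- res$qaly_pf + res$qaly_pd
  res$qaly_pf_undisc <- res$ly_pf_undisc * utility_pf
  res$qaly_pd_undisc <- res$ly_pd_undisc * utility_pd
  res$qaly_total_undisc <- res$qaly_pf_undisc + res$qaly_pd_undisc
  res$discount_rate <- discount
  structure(res, class = "econ_result")
}

#' Run the cohort model for one arm
#'
#' Simulates the three-state semi-Markov cohort on the cycle grid. Per cycle
#' `[t0, t1)`: the probability of leaving PF is `1 - S_pfs(t1)/S_pfs(t0)`, of
#' progressing `1 - S_ttp(t1)/S_ttp(t0)`, and PF-to-death is their difference
#' floored at 0. New PD entrants start a time-since-progression clock at 0;
#' each tunnel cohort with elapsed time `u` advances to death with probability
#' `1 - S_pps(u + dt)/S_pps(u)`. Life-years accrue as occupancy at cycle
#' start times cycle length; QALYs additionally weight by the state utility;
#' discounting applies `(1 + discount)^(-t_mid/12)` at the cycle midpoint.
#'
#' @param arm An [arm_spec()].
#' @param grid A [build_cycle_grid()] grid.
#' @param discount Annual discount rate (default 0.05).
#' @param half_cycle Apply the half-cycle correction (average of start- and
#'   end-of-cycle occupancy); default `FALSE`.
#' @param pps_clock `"since_progression"` (tunnel clock resets at progression;
#'   default) or `"model_time"` (PPS evaluated on the model clock).
#' @param keep_tunnel Keep the full PD-occupancy-by-tunnel matrix as
#'   attribute `"pd_tunnel"` of the trace (memory grows with the square of
#'   the cycle count).
#' @return List with `trace` (a `cohort_trace` data frame: one row per cycle
#'   with state occupancies at cycle start and incident events) and `econ`
#'   (an `econ_result` with discounted/undiscounted LY and QALY by state).
#' @export
run_cohort <- function(arm, grid, discount = 0.05, half_cycle = FALSE,
                       pps_clock = c("since_progression", "model_time"),
                       keep_tunnel = FALSE) {
  stopifnot(inherits(arm, "arm_spec"), inherits(grid, "cycle_grid"))
  if (!is.finite(discount) || discount < 0)
    stop("discount must be a non-negative rate")
  st <- .compute_trace(arm, grid, pps_clock)
  n <- grid$n_cycles
  trace <- data.frame(
    cycle = seq_len(n),
    t_start = grid$boundaries[1:n],
    t_end = grid$boundaries[-1],
    pf = st$pf[1:n], pd = st$pd[1:n], dead = st$dead[1:n],
    incident_progressions = st$entrants,
    incident_deaths = st$pf_deaths + st$pd_deaths)
  class(trace) <- c("cohort_trace", "data.frame")
  attr(trace, "arm") <- arm$name
  attr(trace, "entrants") <- st$entrants
  attr(trace, "pps_clock") <- st$pps_clock
  if (keep_tunnel && st$pps_clock == "since_progression") {
    entry <- grid$boundaries[-1]
    off <- outer(grid$boundaries[1:n], entry, "-")
    keep <- off >= -1e-12
    tun <- matrix(0, n, n)
    tun[keep] <- surv_prob(arm$pps, pmax(off[keep], 0))
    attr(trace, "pd_tunnel") <- sweep(tun, 2, st$entrants, "*")
  }
  econ <- .accrue_econ(st, grid, discount, arm$utility_pf, arm$utility_pd,
                       half_cycle)
  list(trace = trace, econ = econ)
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf(paste0("<econ_result> discount %.1f%%\n",
                     "  LY   PF %.4f  PD %.4f  total %.4f (undisc %.4f)\n",
                     "  QALY PF %.4f  PD %.4f  total %.4f (undisc %.4f)\n"),
              100 * x$discount_rate, x$ly_pf, x$ly_pd, x$ly_total,
              x$ly_total_undisc, x$qaly_pf, x$qaly_pd, x$qaly_total,
              x$qaly_total_undisc))
  invisible(x)
}

#' Convert an economic result to a one-row data frame
#' @param x An `econ_result`.
#' @param ... Unused.
#' @return One-row data frame.
#' @export
as.data.frame.econ_result <- function(x, ...) {
  as.data.frame(unclass(x))
}

#' Write a cohort trace to CSV
#'
#' One row per cycle: times, state occupancies at cycle start, incident
#' progressions and deaths. The file round-trips losslessly through
#' [read_trace()] (within 1e-12).
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  ok <- tryCatch({
    utils::write.csv(format(as.data.frame(trace), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write trace to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a cohort trace from CSV
#' @param path Path written by [write_trace()].
#' @return A `cohort_trace` data frame.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  d <- utils::read.csv(path)
  class(d) <- c("cohort_trace", "data.frame")
  d
}
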