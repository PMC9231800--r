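#' Configuration for the synthetic patient-level data generator
#'
#' Emulates the statistical structure the analysis assumes for its (non
#' deposited) trial inputs: right-censored TTP/PFS/PPS times drawn from
#' specified parametric curves per arm, and longitudinal EQ-5D-like utility
#' observations clustered by patient with state-specific means.
#'
#' @param n_per_arm Patients per arm.
#' @param arms Named list of arms, each a list with `ttp`, `pfs`, `pps`
#'   [surv_curve()]s. Default: the shipped base-case curves.
#' @param censor_time Administrative censoring time (months).
#' @param utility_pf,utility_pd True state mean utilities.
#' @param sd_between Between-patient SD of the random intercept.
#' @param sd_resid Residual SD of a single utility observation.
#' @param assess_interval Months between utility assessments.
#' @param seed RNG seed (mandatory).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_per_arm = 200, arms = NULL, censor_time = 36,
                       utility_pf = 0.901, utility_pd = 0.863,
                       sd_between = 0.05, sd_resid = 0.05,
                       assess_interval = 1.5, seed) {
  if (missing(seed)) stop("a seed is mandatory for the generator")
  if (is.null(arms)) {
    cfg <- default_config()
    arms <- lapply(cfg$arms, function(a)
      list(ttp = .curve_from_spec(a$ttp, cfg$conventions),
           pfs = .curve_from_spec(a$pfs, cfg$conventions),
           pps = .curve_from_spec(a$pps, cfg$conventions)))
  }
  stopifnot(n_per_arm >= 1, censor_time > 0, sd_between >= 0, sd_resid >= 0,
            utility_pf >= 0, utility_pf <= 1, utility_pd >= 0,
            utility_pd <= 1, assess_interval > 0)
  for (a in arms) for (cv in a[c("ttp", "pfs", "pps")]) .check_curve(cv)
  structure(list(n_per_arm = n_per_arm, arms = arms,
                 censor_time = censor_time, utility_pf = utility_pf,
                 utility_pd = utility_pd, sd_between = sd_between,
                 sd_resid = sd_resid, assess_interval = assess_interval,
                 seed = seed), class = "sim_config")
}

# Draw pre-progression death times with hazard max(0, h_pfs - h_ttp) by
# inverting the cumulative excess hazard on a dense grid (exact in law).
# Returns Inf where no death occurs before `tmax` (censoring handles it).
.draw_excess_death <- function(n, pfs, ttp, tmax) {
  # stop the hazard grid before PFS survival underflows (the surviving
  # fraction beyond the cap is below 1e-12 and cannot influence the draws)
  t_cap <- tryCatch(.dist_fun(pfs, "q")(1e-12, lower.tail = FALSE),
                    error = function(e) tmax)
  tmax <- min(tmax, t_cap)
  tg <- seq(0, tmax, length.out = 4001)[-1]
  h_pfs <- surv_hazard(pfs, tg)
  h_ttp <- surv_hazard(ttp, tg)
  # curves must be consistent: PFS survival cannot materially exceed TTP
  # survival (sub-1e-3 excursions are tolerated as fitting noise between
  # independently fitted curves; the excess hazard is floored at 0 there,
  # mirroring the cohort engine's PF exit split)
  s_pfs <- surv_prob(pfs, tg)
  s_ttp <- surv_prob(ttp, tg)
  bad <- which(s_pfs > s_ttp + 1e-3)
  if (length(bad))
    stop(sprintf(
      "inconsistent curves: S_pfs > S_ttp at t = %.4f months (and %d more)",
      tg[bad[1]], length(bad) - 1L))
  h <- pmax(0, h_pfs - h_ttp)
  dt <- diff(c(0, tg))
  H <- cumsum((h + c(h[1], h[-length(h)])) / 2 * dt)  # trapezoid from 0
  E <- rexp(n)
  out <- rep(Inf, n)
  reach <- E <= H[length(H)]
  out[reach] <- stats::approx(c(0, H), c(0, tg), xout = E[reach],
                              ties = "ordered")$y
  out
}

#' Simulate right-censored individual patient data
#'
#' Per patient: a progression time from the TTP curve; a pre-progression
#' death time with hazard `max(0, h_pfs - h_ttp)` (mirroring the cohort
#' engine's PF exit split, so simulation and model are mutually consistent);
#' for progressors, a post-progression survival time from the PPS curve.
#' Administrative right-censoring applies at `censor_time`.
#'
#' @param config A [sim_config()].
#' @return Named list per arm, each with data frames `ttp`, `pfs`, `pps`
#'   (columns `time`, `event`) and `patients` (`id`, `t_prog`, `t_death_pre`,
#'   `t_pps`, `censor_time`).
#' @export
simulate_ipd <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  C <- config$censor_time
  out <- lapply(names(config$arms), function(arm_name) {
    a <- config$arms[[arm_name]]
    n <- config$n_per_arm
    t_prog <- surv_rand(n, a$ttp)
    t_dpre <- .draw_excess_death(n, a$pfs, a$ttp, tmax = C)
    progressed <- t_prog < pmin(t_dpre, C)
    t_pps <- rep(NA_real_, n)
    t_pps[progressed] <- surv_rand(sum(progressed), a$pps)
    ttp <- data.frame(time = pmin(t_prog, t_dpre, C),
                      event = as.integer(t_prog <= pmin(t_dpre, C)))
    exit <- pmin(t_prog, t_dpre)
    pfs <- data.frame(time = pmin(exit, C),
                      event = as.integer(exit <= C))
    pps <- if (any(progressed)) {
      left <- C - t_prog[progressed]
      data.frame(time = pmin(t_pps[progressed], left),
                 event = as.integer(t_pps[progressed] <= left))
    } else data.frame(time = numeric(), event = integer())
    patients <- data.frame(id = paste0(arm_name, "_", seq_len(n)),
                           t_prog = t_prog, t_death_pre = t_dpre,
                           t_pps = t_pps, censor_time = C)
    list(ttp = ttp, pfs = pfs, pps = pps, patients = patients)
  })
  names(out) <- names(config$arms)
  out
}

#' Simulate longitudinal utility observations
#'
#' Assessments every `assess_interval` months from entry until death or
#' censoring. Each observation is the state mean plus a patient random
#' intercept (`Normal(0, sd_between)`) plus residual noise
#' (`Normal(0, sd_resid)`), clamped to the instrument range `[-0.5, 1]`.
#' State at assessment is PF before progression, PD after.
#'
#' @param config A [sim_config()].
#' @param ipd Output of [simulate_ipd()] under the same config.
#' @return Data frame: `patient`, `time`, `state` (`"PF"`/`"PD"`), `value`.
#' @export
simulate_utilities <- function(config, ipd) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  rows <- list()
  for (arm_name in names(ipd)) {
    p <- ipd[[arm_name]]$patients
    for (i in seq_len(nrow(p))) {
      t_prog <- p$t_prog[i]
      death <- if (t_prog < p$t_death_pre[i] && !is.na(p$t_pps[i]))
        t_prog + p$t_pps[i] else p$t_death_pre[i]
      follow <- min(death, p$censor_time[i])
      if (follow <= 0) next
      times <- seq(0, follow, by = config$assess_interval)
      state <- ifelse(times < min(t_prog, p$t_death_pre[i]), "PF", "PD")
      # no assessments in PD unless the patient actually progressed
      if (t_prog >= p$t_death_pre[i]) state[state == "PD"] <- NA
      keep <- !is.na(state)
      if (!any(keep)) next
      b_i <- rnorm(1, 0, config$sd_between)
      mu <- ifelse(state[keep] == "PF", config$utility_pf, config$utility_pd)
      val <- mu + b_i + rnorm(sum(keep), 0, config$sd_resid)
      rows[[length(rows) + 1L]] <-
        data.frame(patient = p$id[i], time = times[keep],
                   state = state[keep],
                   value = pmin(pmax(val, -0.5), 1))
    }
  }
  if (!length(rows))
    return(data.frame(patient = character(), time = numeric(),
                      state = character(), value = numeric()))
  do.call(rbind, rows)
}

#' Estimate state mean utilities with patient clustering
#'
#' Two-level random-intercept estimator: state fixed effects plus a patient
#' random intercept, fitted with [lme4::lmer()]. Degenerate (zero-noise)
#' data are detected and resolved by direct state means with zero SE; if the
#' mixed-model fit fails, a two-stage estimator (patient-by-state means,
#' then state means across patients) is used instead.
#'
#' @param observations Data frame as produced by [simulate_utilities()].
#' @return List: `mean_pf`, `mean_pd`, `se_pf`, `se_pd`, `method`,
#'   `n_patients`. A state with no observations yields `NA` estimates and is
#'   named in `inestimable`.
#' @export
estimate_state_utilities <- function(observations) {
  stopifnot(is.data.frame(observations),
            all(c("patient", "state", "value") %in% names(observations)))
  n_pat <- length(unique(observations$patient))
  if (n_pat < 2) stop("need at least 2 patients")
  states <- c("PF", "PD")
  missing_states <- setdiff(states, unique(observations$state))
  out <- list(mean_pf = NA_real_, mean_pd = NA_real_,
              se_pf = NA_real_, se_pd = NA_real_,
              n_patients = n_pat, inestimable = missing_states)
  if (length(missing_states)) {
    have <- setdiff(states, missing_states)
    for (stt in have) {
      v <- observations$value[observations$state == stt]
      out[[paste0("mean_", tolower(stt))]] <- mean(v)
      out[[paste0("se_", tolower(stt))]] <- sd(v) / sqrt(length(v))
    }
    out$method <- "single-state means"
    return(out)
  }
  within_dev <- vapply(states, function(stt) {
    v <- observations$value[observations$state == stt]
    max(abs(v - mean(v)))
  }, numeric(1))
  if (max(within_dev) < 1e-10) {
    out$mean_pf <- mean(observations$value[observations$state == "PF"])
    out$mean_pd <- mean(observations$value[observations$state == "PD"])
    out$se_pf <- out$se_pd <- 0
    out$method <- "degenerate (zero noise)"
    return(out)
  }
  observations$state <- factor(observations$state, levels = states)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(value ~ 0 + state + (1 | patient), data = observations))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    out$mean_pf <- unname(fe[["statePF"]])
    out$mean_pd <- unname(fe[["statePD"]])
    out$se_pf <- unname(se[[which(names(fe) == "statePF")]])
    out$se_pd <- unname(se[[which(names(fe) == "statePD")]])
    out$method <- "random-intercept (lmer)"
    return(out)
  }
  # fallback: patient-by-state means, then state means across patients
  agg <- stats::aggregate(value ~ patient + state, observations, mean)
  for (stt in states) {
    v <- agg$value[agg$state == stt]
    out[[paste0("mean_", tolower(stt))]] <- mean(v)
    out[[paste0("se_", tolower(stt))]] <- sd(v) / sqrt(length(v))
  }
  out$method <- "two-stage means"
  out
}

#' Write utility observations to CSV
#' @param observations Data frame from [simulate_utilities()].
#' @param path Output path.
#' @export
write_utilities <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE)
  invisible(path)
}
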