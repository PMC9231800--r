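#' Define a vial set
#'
#' @param sizes_mg Vial sizes in mg.
#' @param prices Unit prices (RMB), same length.
#' @return Object of class `vial_set`.
#' @examples
#' vial_set(c(120, 500), c(6066, 18088))  # durvalumab retail prices
#' @export
vial_set <- function(sizes_mg, prices) {
  if (!length(sizes_mg)) stop("vial set must be non-empty")
  if (length(sizes_mg) != length(prices))
    stop("sizes and prices must have the same length")
  if (any(sizes_mg <= 0) || any(prices <= 0))
    stop("vial sizes and prices must be positive")
  structure(list(sizes_mg = as.numeric(sizes_mg),
                 prices = as.numeric(prices)), class = "vial_set")
}

#' Cheapest vial combination covering a dose
#'
#' Minimal total price over non-negative integer vial counts whose total mg
#' is at least the dose (no vial sharing; wastage is paid). Solved by bounded
#' exhaustive search: each size's count is bounded by `ceiling(dose/size)`.
#'
#' @param dose_mg Dose in mg, `> 0`.
#' @param vials A [vial_set()].
#' @return Cost in the vial set's currency, with attribute `"counts"` giving
#'   one optimal combination.
#' @examples
#' administration_cost(612, vial_set(c(120, 500), c(6066, 18088)))  # 24154
#' @export
administration_cost <- function(dose_mg, vials) {
  if (!inherits(vials, "vial_set")) stop("expected a 'vial_set'")
  if (!is.finite(dose_mg) || dose_mg <= 0) stop("dose must be positive")
  sizes <- vials$sizes_mg
  prices <- vials$prices
  k <- length(sizes)
  best <- list(cost = Inf, counts = integer(k))
  counts <- integer(k)
  recurse <- function(i, remaining, cost_so_far) {
    if (cost_so_far >= best$cost) return()
    if (remaining <= 0) {
      best <<- list(cost = cost_so_far, counts = counts)
      return()
    }
    if (i > k) return()
    if (i == k) {
      # last size must cover the remainder
      m <- ceiling(remaining / sizes[i])
      counts[i] <<- m
      recurse(i + 1L, remaining - m * sizes[i], cost_so_far + m * prices[i])
      counts[i] <<- 0L
      return()
    }
    for (m in 0:ceiling(remaining / sizes[i])) {
      counts[i] <<- m
      recurse(i + 1L, remaining - m * sizes[i], cost_so_far + m * prices[i])
    }
    counts[i] <<- 0L
  }
  recurse(1L, dose_mg, 0)
  structure(best$cost, counts = best$counts)
}

#' Dosing schedule
#'
#' Default reflects durvalumab 10 mg/kg every 14 days for up to 12 months or
#' until progression, at the cohort's fixed 61.2 kg body weight.
#'
#' @param dose_per_kg mg per kg per administration.
#' @param body_weight kg.
#' @param frequency_days Days between administrations.
#' @param max_duration_months Treatment cap in months.
#' @param stop_on_progression Treatment stops at progression.
#' @return Object of class `dose_schedule`; `$dose_mg` is the per-administration dose.
#' @export
dose_schedule <- function(dose_per_kg = 10, body_weight = 61.2,
                          frequency_days = 14, max_duration_months = 12,
                          stop_on_progression = TRUE) {
  if (dose_per_kg <= 0 || body_weight <= 0)
    stop("dose and weight must be positive")
  structure(list(dose_per_kg = dose_per_kg, body_weight = body_weight,
                 dose_mg = dose_per_kg * body_weight,
                 frequency_days = frequency_days,
                 max_duration_months = max_duration_months,
                 stop_on_progression = stop_on_progression),
            class = "dose_schedule")
}

#' Patient Assistance Program schedule
#'
#' Staged buy-some-get-some relief: the patient pays for `stage1_paid`
#' administrations and receives `stage1_free` free; after paying for
#' `stage2_paid` more, all further administrations are free until progression
#' (within the treatment cap). Defaults: 2 paid, 2 free, 4 paid, then free.
#'
#' @param stage1_paid,stage1_free,stage2_paid Non-negative integer
#'   administration counts.
#' @return Object of class `pap_schedule`.
#' @export
pap_schedule <- function(stage1_paid = 2, stage1_free = 2, stage2_paid = 4) {
  counts <- c(stage1_paid, stage1_free, stage2_paid)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("PAP counts must be non-negative integers")
  structure(list(stage1_paid = stage1_paid, stage1_free = stage1_free,
                 stage2_paid = stage2_paid), class = "pap_schedule")
}

# indices (1-based administration number) the patient pays for under PAP
.pap_paid_indices <- function(pap, n_admin) {
  s1p <- pap$stage1_paid
  s1f <- pap$stage1_free
  s2p <- pap$stage2_paid
  paid <- c(seq_len(s1p), s1p + s1f + seq_len(s2p))
  paid[paid <= n_admin]
}

#' Per-cycle payable drug cost vector
#'
#' One administration per first-phase cycle while on treatment (the dosing
#' frequency must match the grid's first-phase cycle length), up to the
#' treatment-duration cap; zero thereafter. Under the assistance program only
#' the paid administrations carry cost. The engine multiplies this vector by
#' PF occupancy (treatment stops at progression).
#'
#' @param schedule A [dose_schedule()].
#' @param vials A [vial_set()] for the drug.
#' @param grid A [build_cycle_grid()].
#' @param pap A [pap_schedule()] or `NULL` for retail pricing throughout.
#' @return Numeric vector, length `grid$n_cycles`: payable cost per cycle.
#' @export
drug_cost_schedule <- function(schedule, vials, grid, pap = NULL) {
  stopifnot(inherits(schedule, "dose_schedule"), inherits(grid, "cycle_grid"))
  if (abs(schedule$frequency_days - grid$first_cycle_days) > 1e-9)
    stop("dosing frequency must align with the grid's first-phase cycle")
  per_admin <- as.numeric(administration_cost(schedule$dose_mg, vials))
  n_admin <- min(grid$n_first_phase,
                 floor(schedule$max_duration_months * DAYS_PER_MONTH /
                         schedule$frequency_days))
  cost <- numeric(grid$n_cycles)
  if (is.null(pap)) {
    cost[seq_len(n_admin)] <- per_admin
  } else {
    stopifnot(inherits(pap, "pap_schedule"))
    if (pap$stage1_paid + pap$stage1_free + pap$stage2_paid > n_admin)
      stop("PAP stage counts exceed the number of administrations")
    cost[.pap_paid_indices(pap, n_admin)] <- per_admin
  }
  cost
}

#' Cost configuration
#'
#' Recurring resource-use costs are monthly rates multiplied by state
#' occupancy and cycle length; terminal care is a one-off applied to incident
#' deaths; adverse-event treatment is a one-off expected cost applied at
#' model entry. Values the source publication does not print default to 0
#' and carry `source = "placeholder"`.
#'
#' @param pf_monthly,pd_monthly Monthly medical-resource cost (medical
#'   service + inspections) while in PF / PD (RMB/month).
#' @param subsequent Data frame with columns `label`, `proportion`,
#'   `monthly`: the post-progression treatment mix; proportions must sum to
#'   at most 1. Applied to PD occupancy.
#' @param terminal One-off terminal-care cost at death.
#' @param ae_entry One-off expected adverse-event cost at model entry
#'   (incidence-weighted).
#' @param source Provenance tag echoed into run manifests.
#' @return Object of class `cost_config`.
#' @export
cost_config <- function(pf_monthly = 0, pd_monthly = 0,
                        subsequent = NULL, terminal = 0, ae_entry = 0,
                        source = "placeholder") {
  if (is.null(subsequent))
    subsequent <- data.frame(label = character(), proportion = numeric(),
                             monthly = numeric())
  stopifnot(is.data.frame(subsequent),
            all(c("label", "proportion", "monthly") %in% names(subsequent)))
  if (nrow(subsequent) && sum(subsequent$proportion) > 1 + 1e-9)
    stop("subsequent-treatment proportions must sum to <= 1")
  vals <- c(pf_monthly, pd_monthly, terminal, ae_entry, subsequent$monthly,
            subsequent$proportion)
  if (any(vals < 0)) stop("costs and proportions must be >= 0")
  structure(list(pf_monthly = pf_monthly, pd_monthly = pd_monthly,
                 subsequent = subsequent, terminal = terminal,
                 ae_entry = ae_entry, source = source),
            class = "cost_config")
}

#' Accrue discounted costs over a cohort trace
#'
#' Components: drug cost vector times PF occupancy; PF/PD monthly resource
#' costs times occupancy-months; subsequent-treatment mix times PD
#' occupancy-months; terminal care times incident deaths; adverse-event
#' expectation as a one-off at model entry. Each cycle's accrual is
#' discounted at its midpoint. The total equals the sum of components
#' exactly.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param config A [cost_config()].
#' @param grid The grid the trace was computed on.
#' @param drug_vector Per-cycle payable drug cost ([drug_cost_schedule()]),
#'   or `NULL` for a zero-drug-cost arm.
#' @param discount Annual discount rate.
#' @return Object of class `cost_result`: `components` and
#'   `components_undisc` (named vectors), `total`, `total_undisc`.
#' @export
accrue_costs <- function(trace, config, grid, drug_vector = NULL,
                         discount = 0.05) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(config, "cost_config"),
            inherits(grid, "cycle_grid"))
  n <- grid$n_cycles
  if (nrow(trace) != n) stop("trace and grid have different cycle counts")
  if (is.null(drug_vector)) drug_vector <- numeric(n)
  if (length(drug_vector) != n)
    stop("drug_vector length must equal the cycle count")
  w <- (1 + discount)^(-grid$midpoints / 12)
  dl <- grid$lengths
  sub_monthly <- if (nrow(config$subsequent))
    sum(config$subsequent$proportion * config$subsequent$monthly) else 0
  comp <- function(wt) c(
    drug        = sum(drug_vector * trace$pf * wt),
    pf_medical  = sum(config$pf_monthly * trace$pf * dl * wt),
    pd_medical  = sum(config$pd_monthly * trace$pd * dl * wt),
    subsequent  = sum(sub_monthly * trace$pd * dl * wt),
    terminal    = sum(config$terminal * trace$incident_deaths * wt),
    adverse_events = config$ae_entry)
  components <- comp(w)
  components_undisc <- comp(rep(1, n))
  structure(list(components = components,
                 components_undisc = components_undisc,
                 total = sum(components),
                 total_undisc = sum(components_undisc),
                 discount_rate = discount),
            class = "cost_result")
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf("<cost_result> total %.2f RMB discounted (%.2f undiscounted)\n",
              x$total, x$total_undisc))
  print(round(x$components, 2))
  invisible(x)
}
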