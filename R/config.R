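#' @importFrom utils modifyList write.csv packageVersion
NULL

# Published survival-curve parameters (location/scale/shape per arm and
# role; the gengamma shape column is stored raw and mapped to the signed
# shape Q by the convention switch).
.curve_table <- function() {
  list(
    durvalumab = list(
      ttp = list(family = "gengamma",
                 params = list(beta = 0.6323, sigma = 0.6480, k = 7.3951),
                 source = "table1"),
      pfs = list(family = "gengamma",
                 params = list(beta = 0.6478, sigma = 0.6448, k = 6.9943),
                 source = "table1"),
      pps = list(family = "lognormal",
                 params = list(meanlog = 3.0448, sdlog = 1.1876),
                 source = "table1")),
    bsc = list(
      ttp = list(family = "gengamma",
                 params = list(beta = 0.6384, sigma = 0.5739, k = 4.2698),
                 source = "table1"),
      pfs = list(family = "gengamma",
                 params = list(beta = 0.6274, sigma = 0.5416, k = 4.0697),
                 source = "table1"),
      pps = list(family = "lognormal",
                 params = list(meanlog = 3.0448, sdlog = 1.1876),
                 source = "table1")))
}

# Unit prices and other uncertain parameters with their PSA distributions
# (unit prices in RMB; SEs are 10% of the base where no SE was published).
.default_param_table <- function() {
  P <- function(...) param_spec(...)
  rbind(
    P("price_durvalumab_120", 6066, 606.60, 4935.54, 7311.29, "gamma"),
    P("price_durvalumab_500", 18088, 1808.80, 14717.12, 21801.28, "gamma"),
    P("price_nivolumab_40", 4587, 458.70, 3732.17, 5528.66, "gamma"),
    P("price_nivolumab_100", 9250, 925.00, 7526.17, 11148.93, "gamma"),
    P("price_pembrolizumab_100", 17918, 1791.80, 14578.80, 21596.38, "gamma"),
    P("price_docetaxel_20", 302.4, 30.24, 246.04, 364.48, "gamma"),
    P("price_vinorelbine_10", 126.9, 12.69, 103.25, 152.95, "gamma"),
    P("price_erlotinib_box", 1275.75, 127.58, 1038.00, 1537.65, "gamma"),
    P("price_crizotinib_box", 15600, 1560.00, 12692.78, 18802.52, "gamma"),
    P("price_afatinib_box", 1400, 140.00, 1139.10, 1687.41, "gamma"),
    P("price_gemcitabine_1g", 787.72, 78.77, 640.92, 949.43, "gamma"),
    P("price_carboplatin_100", 53.9, 5.39, 43.86, 64.97, "gamma"),
    P("price_cisplatin_30", 19.15, 1.92, 15.58, 23.08, "gamma"),
    P("price_paclitaxel_100", 533.43, 53.34, 434.02, 642.94, "gamma"),
    P("price_pemetrexed_500", 2776.97, 277.70, 2259.45, 3347.05, "gamma"),
    P("price_3dcrt", 30000, 3000.00, 24409.20, 36158.68, "gamma"),
    P("price_imrt", 50000, 5000.00, 40682.00, 60264.47, "gamma"),
    P("price_igimrt", 80000, 8000.00, 65091.19, 96423.16, "gamma"),
    P("price_tomo", 100000, 10000.00, 81363.99, 120528.95, "gamma"),
    P("utility_pf", 0.901, 0.009, 0.883, 0.918, "beta"),
    P("utility_pd", 0.863, 0.009, 0.845, 0.880, "beta"),
    P("discount", 0.05, NA, 0, 0.08, "uniform"),
    P("age", 62.90, 0.34, 62.24, 63.56, "normal"),
    P("weight", 61.2, 0.74, NA, NA, "fixed"))
}

# Illustrative post-progression treatment mix (non-published resource use;
# flagged as placeholder in every run manifest). Monthly cost of each
# regimen is sum(units_per_month * unit price).
.default_subsequent <- function() {
  list(
    list(label = "immunotherapy", proportion = 0.25,
         items = list(list(param = "price_nivolumab_100",
                           units_per_month = 4.3))),
    list(label = "targeted", proportion = 0.25,
         items = list(list(param = "price_erlotinib_box",
                           units_per_month = 4.3))),
    list(label = "chemotherapy", proportion = 0.30,
         items = list(list(param = "price_pemetrexed_500",
                           units_per_month = 2.9),
                      list(param = "price_carboplatin_100",
                           units_per_month = 6.5))),
    list(label = "radiotherapy", proportion = 0.20,
         items = list(list(param = "price_imrt",
                           units_per_month = 0.02))))
}

#' Default run configuration
#'
#' Carries everything the base case needs: the published survival-curve
#' parameters, state utilities 0.901 (PF) / 0.863 (PD), 5\% annual
#' discounting, the 212,676 RMB/QALY willingness-to-pay threshold (three
#' times 2019 Chinese GDP per capita), the 14-day/28-day cycle grid to 480
#' months, the dosing and assistance-program schedules, the published unit
#' prices with their PSA distributions, and placeholder resource-use costs
#' (values the source publication does not print; every placeholder is
#' listed in the run manifest).
#'
#' @param pap Apply the Patient Assistance Program to durvalumab drug cost.
#' @return A named list (a run configuration).
#' @export
default_config <- function(pap = FALSE) {
  list(
    scenario = if (pap) "base_case_pap" else "base_case",
    pap = pap,
    discount = 0.05,
    wtp = 212676,
    utilities = list(pf = 0.901, pd = 0.863),
    grid = list(first_cycle_days = 14, later_cycle_days = 28,
                phase_switch_months = 12, horizon_months = 480),
    conventions = list(gengamma_shape = "negated", half_cycle = FALSE,
                       pps_clock = "since_progression"),
    arms = .curve_table(),
    treatment = list(dose_per_kg = 10, body_weight = 61.2,
                     frequency_days = 14, max_duration_months = 12,
                     vials = list(sizes_mg = c(120, 500),
                                  price_params = c("price_durvalumab_120",
                                                   "price_durvalumab_500"))),
    pap_schedule = list(stage1_paid = 2, stage1_free = 2, stage2_paid = 4),
    costs = list(pf_monthly = 800, pd_monthly = 1200, terminal = 20000,
                 ae_entry = list(durvalumab = 0, bsc = 0),
                 subsequent = .default_subsequent(),
                 source = "placeholder"),
    psa = list(n = 1000),
    params = .default_param_table())
}

# map a stored curve spec + conventions to a surv_curve
.curve_from_spec <- function(spec, conventions) {
  fam <- spec$family
  p <- spec$params
  if (fam == "gengamma") {
    k <- p$k
    Q <- if (identical(conventions$gengamma_shape, "raw")) k else -k
    surv_curve("gengamma", c(mu = p$beta, sigma = p$sigma, Q = Q))
  } else if (fam == "lognormal") {
    surv_curve("lognormal", c(meanlog = p$meanlog, sdlog = p$sdlog))
  } else {
    surv_curve(fam, unlist(p, use.names = FALSE))
  }
}

#' Build one arm's specification from a configuration
#'
#' @param config A run configuration ([default_config()] / [load_config()]).
#' @param arm Arm name (e.g. `"durvalumab"`, `"bsc"`).
#' @return An [arm_spec()].
#' @export
build_arm <- function(config, arm) {
  a <- config$arms[[arm]]
  if (is.null(a)) stop("unknown arm: ", arm)
  arm_spec(arm,
           ttp = .curve_from_spec(a$ttp, config$conventions),
           pfs = .curve_from_spec(a$pfs, config$conventions),
           pps = .curve_from_spec(a$pps, config$conventions),
           utility_pf = config$utilities$pf,
           utility_pd = config$utilities$pd)
}

# ---- validation -----------------------------------------------------------

.assert <- function(ok, field, constraint) {
  if (!isTRUE(ok))
    stop(sprintf("config field '%s': %s", field, constraint), call. = FALSE)
}

.known_keys <- function(config, template, path = "") {
  extra <- setdiff(names(config), names(template))
  if (length(extra))
    stop(sprintf("unknown config key%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste0(path, extra, collapse = ", ")), call. = FALSE)
}

#' Validate a run configuration
#'
#' Rejects unknown top-level keys and violations of the schema constraints
#' (rates, utilities, prices, proportions), naming the offending field.
#'
#' @param config A run-configuration list.
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  .known_keys(config, default_config())
  .assert(is.logical(config$pap) && length(config$pap) == 1, "pap",
          "must be a single logical")
  .assert(is.numeric(config$discount) && config$discount >= 0, "discount",
          "must be a rate >= 0")
  .assert(config$wtp > 0, "wtp", "must be > 0")
  for (u in c("pf", "pd"))
    .assert(config$utilities[[u]] >= 0 && config$utilities[[u]] <= 1,
            paste0("utilities$", u), "must lie in [0, 1]")
  g <- config$grid
  .assert(g$first_cycle_days > 0 && g$later_cycle_days > 0, "grid",
          "cycle lengths must be positive")
  .assert(g$horizon_months > g$phase_switch_months, "grid$horizon_months",
          "must exceed the phase switch")
  .assert(config$conventions$gengamma_shape %in% c("negated", "raw"),
          "conventions$gengamma_shape", "must be 'negated' or 'raw'")
  .assert(config$conventions$pps_clock %in%
            c("since_progression", "model_time"),
          "conventions$pps_clock",
          "must be 'since_progression' or 'model_time'")
  .assert(length(config$arms) >= 2, "arms", "needs at least two arms")
  for (an in names(config$arms))
    for (role in c("ttp", "pfs", "pps"))
      .assert(!is.null(config$arms[[an]][[role]]$family),
              sprintf("arms$%s$%s", an, role), "missing curve spec")
  .assert(config$treatment$body_weight > 0, "treatment$body_weight",
          "must be > 0")
  cc <- config$costs
  for (f in c("pf_monthly", "pd_monthly", "terminal"))
    .assert(cc[[f]] >= 0, paste0("costs$", f), "must be >= 0")
  props <- vapply(cc$subsequent, function(x) x$proportion, numeric(1))
  .assert(all(props >= 0) && sum(props) <= 1 + 1e-9, "costs$subsequent",
          "proportions must be >= 0 and sum to <= 1")
  pt <- config$params
  .check_param_table(pt)
  prices <- pt$base[startsWith(pt$name, "price_")]
  .assert(all(prices >= 0), "params (price_*)", "prices must be >= 0")
  for (vp in config$treatment$vials$price_params)
    .assert(vp %in% pt$name, "treatment$vials$price_params",
            paste("references unknown parameter", vp))
  for (sub in cc$subsequent)
    for (it in sub$items)
      .assert(it$param %in% pt$name,
              sprintf("costs$subsequent (%s)", sub$label),
              paste("references unknown parameter", it$param))
  invisible(config)
}

# ---- YAML round trip ------------------------------------------------------

.params_to_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

.records_to_params <- function(recs) {
  do.call(rbind, lapply(recs, function(r) {
    for (f in c("se", "low", "high"))
      if (is.null(r[[f]]) || !length(r[[f]])) r[[f]] <- NA_real_
    data.frame(name = r$name, base = as.numeric(r$base),
               se = as.numeric(r$se), low = as.numeric(r$low),
               high = as.numeric(r$high), dist = r$dist,
               stringsAsFactors = FALSE)
  }))
}

#' Write a run configuration to YAML
#'
#' @param config A run configuration.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  out <- config
  out$params <- .params_to_records(config$params)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Load and validate a run configuration
#'
#' Missing top-level sections are filled from [default_config()]; unknown
#' keys are rejected; all schema constraints are checked.
#'
#' @param path Path to a YAML configuration.
#' @return The validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$params)) raw$params <- .records_to_params(raw$params)
  if (!is.null(raw$treatment$vials)) {
    raw$treatment$vials$sizes_mg <-
      as.numeric(unlist(raw$treatment$vials$sizes_mg))
    raw$treatment$vials$price_params <-
      as.character(unlist(raw$treatment$vials$price_params))
  }
  .known_keys(raw, default_config())
  config <- modifyList(default_config(), raw)
  if (!is.null(raw$params)) config$params <- raw$params
  if (!is.null(raw$costs$subsequent))
    config$costs$subsequent <- raw$costs$subsequent
  if (!is.null(raw$arms)) config$arms <- raw$arms
  validate_config(config)
  config
}

# ---- resolved model pieces ------------------------------------------------

# named vector of base parameter values
.base_params <- function(config) {
  stats::setNames(config$params$base, config$params$name)
}

.resolve_vials <- function(config, params) {
  v <- config$treatment$vials
  vial_set(v$sizes_mg, unname(params[v$price_params]))
}

.resolve_cost_config <- function(config, params, arm) {
  sub <- do.call(rbind, lapply(config$costs$subsequent, function(s) {
    monthly <- sum(vapply(s$items, function(it)
      it$units_per_month * unname(params[[it$param]]), numeric(1)))
    data.frame(label = s$label, proportion = s$proportion, monthly = monthly,
               stringsAsFactors = FALSE)
  }))
  cost_config(pf_monthly = config$costs$pf_monthly,
              pd_monthly = config$costs$pd_monthly,
              subsequent = sub, terminal = config$costs$terminal,
              ae_entry = config$costs$ae_entry[[arm]],
              source = config$costs$source)
}

.resolve_dose_schedule <- function(config) {
  tr <- config$treatment
  dose_schedule(dose_per_kg = tr$dose_per_kg, body_weight = tr$body_weight,
                frequency_days = tr$frequency_days,
                max_duration_months = tr$max_duration_months)
}

#' Build a model runner for sensitivity analyses
#'
#' Returns a closure evaluating the full two-arm model under a named vector
#' of parameter overrides. Survival curves are held fixed (their traces are
#' precomputed once); utilities, the discount rate and all `price_*`
#' parameters flow through to the accrual and costing stages on every call.
#' `age` and `weight` are accepted for bookkeeping but do not enter the
#' model (weight is fixed in the dose; age only labels the cohort).
#'
#' @param config A run configuration.
#' @return Function `f(overrides)` returning a list with `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `icer`, `label`, `nmb`, and per-arm `arms`.
#' @export
make_model_runner <- function(config) {
  validate_config(config)
  grid <- do.call(build_cycle_grid, config$grid)
  base <- .base_params(config)
  arm_names <- names(config$arms)
  states <- list()
  traces <- list()
  for (an in arm_names) {
    arm <- build_arm(config, an)
    st <- .compute_trace(arm, grid, config$conventions$pps_clock)
    states[[an]] <- st
    n <- grid$n_cycles
    tr <- data.frame(cycle = seq_len(n), t_start = grid$boundaries[1:n],
                     t_end = grid$boundaries[-1], pf = st$pf[1:n],
                     pd = st$pd[1:n], dead = st$dead[1:n],
                     incident_progressions = st$entrants,
                     incident_deaths = st$pf_deaths + st$pd_deaths)
    class(tr) <- c("cohort_trace", "data.frame")
    traces[[an]] <- tr
  }
  sched <- .resolve_dose_schedule(config)
  pap <- if (config$pap) do.call(pap_schedule, config$pap_schedule) else NULL
  half_cycle <- isTRUE(config$conventions$half_cycle)
  intervention <- arm_names[1]
  comparator <- arm_names[2]

  function(overrides = NULL) {
    params <- base
    if (length(overrides)) {
      unknown <- setdiff(names(overrides), names(params))
      if (length(unknown))
        stop("unknown parameter override(s): ",
             paste(unknown, collapse = ", "))
      params[names(overrides)] <- overrides
    }
    # parameters absent from the table stay at their configured base values
    pick <- function(nm, default) {
      if (nm %in% names(params)) unname(params[[nm]]) else default
    }
    disc <- pick("discount", config$discount)
    u_pf <- pick("utility_pf", config$utilities$pf)
    u_pd <- pick("utility_pd", config$utilities$pd)
    vials <- .resolve_vials(config, params)
    arms_out <- list()
    for (an in arm_names) {
      econ <- .accrue_econ(states[[an]], grid, disc, u_pf, u_pd, half_cycle)
      drug <- if (an == intervention)
        drug_cost_schedule(sched, vials, grid, pap) else NULL
      cost <- accrue_costs(traces[[an]], .resolve_cost_config(config, params, an),
                           grid, drug, disc)
      arms_out[[an]] <- list(econ = econ, cost = cost)
    }
    cmp <- compare_arms(arms_out[[intervention]], arms_out[[comparator]],
                        wtp = config$wtp)
    list(delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
         delta_ly = cmp$delta_ly, icer = cmp$icer, label = cmp$label,
         nmb = cmp$nmb, comparison = cmp, arms = arms_out)
  }
}

# ---- orchestrated runs ----------------------------------------------------

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  out <- config
  out$params <- .params_to_records(config$params)
  yaml::write_yaml(out, tmp, precision = 15)
  unname(tools::md5sum(tmp))
}

.placeholders <- function(config) {
  c("costs$pf_monthly", "costs$pd_monthly", "costs$terminal",
    "costs$ae_entry", "costs$subsequent (mix and resource use)")
}

.write_manifest <- function(config, out_dir, seed = NULL, extra = list()) {
  manifest <- c(list(
    scenario = config$scenario,
    config_md5 = .config_hash(config),
    package_version = as.character(utils::packageVersion("durvaCEA")),
    seed = if (is.null(seed)) NA else seed,
    placeholder_values = .placeholders(config)), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.with_cleanup <- function(out_dir, files, expr) {
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(out_dir, files)), add = TRUE)
  force(expr)
  ok <- TRUE
  invisible(NULL)
}

#' Run the base case and write its result files
#'
#' Writes, per arm, the cohort trace and cost components, plus the combined
#' economic results table, the arm comparison, and a run manifest. The
#' LY/QALY outputs do not depend on the assistance-program flag (it affects
#' drug cost only). On any stage failure, partial outputs are removed.
#'
#' @param config A run configuration.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results.
#' @export
run_base_case <- function(config, out_dir) {
  validate_config(config)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  runner <- make_model_runner(config)
  res <- runner()
  arm_names <- names(res$arms)
  files <- c(paste0("trace_", arm_names, ".csv"), "econ_results.csv",
             "costs.csv", "comparison.csv", "manifest.json")
  grid <- do.call(build_cycle_grid, config$grid)
  .with_cleanup(out_dir, files, {
    for (an in arm_names) {
      arm <- build_arm(config, an)
      tr <- run_cohort(arm, grid, discount = config$discount,
                       half_cycle = config$conventions$half_cycle,
                       pps_clock = config$conventions$pps_clock)$trace
      write_trace(tr, file.path(out_dir, paste0("trace_", an, ".csv")))
    }
    econ <- do.call(rbind, lapply(arm_names, function(an)
      cbind(arm = an, as.data.frame(res$arms[[an]]$econ))))
    write.csv(econ, file.path(out_dir, "econ_results.csv"),
              row.names = FALSE)
    costs <- do.call(rbind, lapply(arm_names, function(an) {
      cr <- res$arms[[an]]$cost
      data.frame(arm = an, component = names(cr$components),
                 discounted = round(unname(cr$components), 2),
                 undiscounted = round(unname(cr$components_undisc), 2))
    }))
    write.csv(costs, file.path(out_dir, "costs.csv"), row.names = FALSE)
    write.csv(as.data.frame(res$comparison),
              file.path(out_dir, "comparison.csv"), row.names = FALSE)
    .write_manifest(config, out_dir)
  })
  invisible(res)
}

#' Run the one-way sensitivity analysis and write the tornado table
#'
#' @param config A run configuration.
#' @param out_dir Output directory.
#' @return Invisibly, the tornado data frame.
#' @export
run_owsa_analysis <- function(config, out_dir) {
  validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  runner <- make_model_runner(config)
  tornado <- run_owsa(runner, config$params)
  .with_cleanup(out_dir, c("tornado.csv", "manifest.json"), {
    write.csv(tornado, file.path(out_dir, "tornado.csv"), row.names = FALSE)
    .write_manifest(config, out_dir)
  })
  invisible(tornado)
}

#' Run the probabilistic sensitivity analysis and write its tables
#'
#' Writes the per-draw incremental outcomes (the cost-effectiveness plane),
#' the acceptability curve, a summary row, and a manifest recording the
#' seed.
#'
#' @param config A run configuration.
#' @param out_dir Output directory.
#' @param seed RNG seed (mandatory).
#' @param n Number of draws; default from `config$psa$n`.
#' @return Invisibly, the `psa_result`.
#' @export
run_psa_analysis <- function(config, out_dir, seed, n = NULL) {
  validate_config(config)
  if (missing(seed)) stop("a seed is mandatory for the PSA")
  if (is.null(n)) n <- config$psa$n
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  runner <- make_model_runner(config)
  psa <- run_psa(runner, config$params, n = n, seed = seed,
                 wtp = config$wtp)
  cc <- ceac(psa)
  files <- c("psa_samples.csv", "ceac.csv", "psa_summary.csv",
             "manifest.json")
  .with_cleanup(out_dir, files, {
    write.csv(psa$samples, file.path(out_dir, "psa_samples.csv"),
              row.names = FALSE)
    write.csv(cc, file.path(out_dir, "ceac.csv"), row.names = FALSE)
    write.csv(as.data.frame(psa$summary),
              file.path(out_dir, "psa_summary.csv"), row.names = FALSE)
    .write_manifest(config, out_dir, seed = seed,
                    extra = list(psa_n = n))
  })
  invisible(psa)
}
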