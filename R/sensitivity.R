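#' @importFrom stats rnorm runif rgamma rbeta qnorm sd var
NULL

#' Define an uncertain parameter
#'
#' @param name Parameter name (must be understood by the model runner; see
#'   [make_model_runner()] for the names the shipped configuration maps).
#' @param base Base-case value.
#' @param se Standard error (`NA` allowed for `uniform`/`fixed`).
#' @param low,high 95\% interval bounds used by the one-way sensitivity
#'   analysis and by the `uniform` distribution; when absent, OWSA falls
#'   back to `base +/- 1.96 se`.
#' @param dist `"gamma"`, `"beta"`, `"normal"`, `"uniform"` or `"fixed"`.
#' @return One-row data frame (rows combine with `rbind`).
#' @export
param_spec <- function(name, base, se = NA_real_, low = NA_real_,
                       high = NA_real_, dist = "fixed") {
  dist <- match.arg(dist, c("gamma", "beta", "normal", "uniform", "fixed"))
  if (!is.na(low) && !is.na(high) && !(low <= base && base <= high))
    stop(sprintf("parameter '%s': need low <= base <= high", name))
  if (!is.na(se) && se < 0) stop("se must be >= 0")
  if (dist == "beta" && (base < 0 || base > 1))
    stop(sprintf("parameter '%s': beta requires a [0,1] quantity", name))
  if (dist == "uniform" && (is.na(low) || is.na(high)))
    stop(sprintf("parameter '%s': uniform requires low and high", name))
  data.frame(name = name, base = base, se = se, low = low, high = high,
             dist = dist, stringsAsFactors = FALSE)
}

.check_param_table <- function(specs) {
  stopifnot(is.data.frame(specs),
            all(c("name", "base", "se", "low", "high", "dist") %in%
                  names(specs)))
  if (anyDuplicated(specs$name)) stop("duplicate parameter names")
  invisible(specs)
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' Distributions are moment-matched to (base, SE): gamma with
#' `shape = (base/se)^2`, `scale = se^2/base`; beta by matching mean and SE;
#' normal(base, se); uniform(low, high); `fixed` returns the base value.
#' An SE of 0 (or `NA` for `fixed`) yields degenerate draws at the base.
#'
#' @param specs Parameter table ([param_spec()] rows).
#' @param n Number of draws (`>= 1`).
#' @param seed RNG seed (draws are reproducible given the seed).
#' @return Data frame, `n` rows, one column per parameter.
#' @export
sample_params <- function(specs, n, seed) {
  .check_param_table(specs)
  stopifnot(n >= 1)
  set.seed(seed)
  out <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    if (s$dist == "fixed" || (!is.na(s$se) && s$se == 0 &&
                              s$dist %in% c("gamma", "beta", "normal")))
      return(rep(s$base, n))
    switch(s$dist,
      gamma = {
        if (is.na(s$se)) stop("gamma parameter '", s$name, "' needs an SE")
        if (s$base <= 0) stop("gamma parameter '", s$name,
                              "' needs a positive base")
        rgamma(n, shape = (s$base / s$se)^2, scale = s$se^2 / s$base)
      },
      beta = {
        if (is.na(s$se)) stop("beta parameter '", s$name, "' needs an SE")
        v <- s$se^2
        if (v >= s$base * (1 - s$base))
          stop(sprintf(
            "beta moment matching infeasible for parameter '%s' (SE too large)",
            s$name))
        nu <- s$base * (1 - s$base) / v - 1
        rbeta(n, shape1 = s$base * nu, shape2 = (1 - s$base) * nu)
      },
      normal = {
        if (is.na(s$se)) stop("normal parameter '", s$name, "' needs an SE")
        rnorm(n, s$base, s$se)
      },
      uniform = runif(n, s$low, s$high))
  })
  names(out) <- specs$name
  as.data.frame(out, check.names = FALSE)
}

.owsa_bounds <- function(s) {
  if (s$dist == "fixed") return(c(s$base, s$base))
  if (!is.na(s$low) && !is.na(s$high)) return(c(s$low, s$high))
  if (!is.na(s$se)) return(c(s$base - 1.96 * s$se, s$base + 1.96 * s$se))
  c(s$base, s$base)
}

#' One-way sensitivity analysis (tornado table)
#'
#' Each parameter is moved to its lower and upper bound (95\% interval when
#' printed, otherwise `base +/- 1.96 SE`; `fixed` parameters do not move)
#' with all others at base, and the ICER recomputed. Rows are sorted by
#' absolute ICER swing, descending (tornado order). A perturbation under
#' which the incremental QALY is not positive is flagged, not dropped.
#'
#' @param runner Model runner from [make_model_runner()]: a function taking a
#'   named vector of parameter overrides and returning a list with at least
#'   `icer`, `delta_qaly`, `delta_cost`, `label`.
#' @param specs Parameter table.
#' @return Data frame: `parameter`, `low`, `high`, `icer_low`, `icer_high`,
#'   `swing`, `note`.
#' @export
run_owsa <- function(runner, specs) {
  .check_param_table(specs)
  eval_at <- function(name, value) {
    ov <- stats::setNames(value, name)
    res <- runner(ov)
    list(icer = res$icer, label = res$label)
  }
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    bd <- .owsa_bounds(s)
    lo <- eval_at(s$name, bd[1])
    hi <- eval_at(s$name, bd[2])
    note <- ""
    if (is.na(lo$icer) || is.na(hi$icer))
      note <- "dominated/undefined at a bound"
    swing <- if (note == "") abs(hi$icer - lo$icer) else NA_real_
    data.frame(parameter = s$name, low = bd[1], high = bd[2],
               icer_low = lo$icer, icer_high = hi$icer, swing = swing,
               note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(ifelse(is.na(out$swing), -Inf, out$swing),
            decreasing = TRUE), , drop = FALSE]
}

#' Probabilistic sensitivity analysis
#'
#' `n` Monte-Carlo draws of all uncertain parameters, each evaluated through
#' the full model. Summary statistics follow the ratio-of-means convention:
#' the reported PSA ICER is mean incremental cost over mean incremental
#' QALYs; the probability of cost-effectiveness is the fraction of draws
#' with positive net monetary benefit at the threshold.
#'
#' @inheritParams run_owsa
#' @param n Number of draws.
#' @param seed RNG seed.
#' @param wtp Willingness-to-pay threshold.
#' @return Object of class `psa_result`: `samples` (draw, delta_cost,
#'   delta_qaly, nmb), `params` (the sampled parameter sets), `summary`
#'   (mean_delta_cost, mean_delta_qaly, icer, prob_ce, n, n_failed),
#'   `failures`.
#' @export
run_psa <- function(runner, specs, n = 1000, seed, wtp = 212676) {
  .check_param_table(specs)
  if (missing(seed)) stop("a seed is mandatory for the PSA")
  draws <- sample_params(specs, n, seed)
  dc <- dq <- rep(NA_real_, n)
  failures <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch(runner(unlist(draws[i, , drop = FALSE])),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("draw %d: %s", i, conditionMessage(res)))
      next
    }
    dc[i] <- res$delta_cost
    dq[i] <- res$delta_qaly
  }
  if (length(failures) > 0.01 * n)
    stop("more than 1% of PSA draws failed; first failure: ", failures[1])
  ok <- !is.na(dc)
  samples <- data.frame(draw = seq_len(n)[ok], delta_cost = dc[ok],
                        delta_qaly = dq[ok],
                        nmb = nmb_vec(dc[ok], dq[ok], wtp))
  summary <- list(mean_delta_cost = mean(samples$delta_cost),
                  mean_delta_qaly = mean(samples$delta_qaly),
                  icer = mean(samples$delta_cost) / mean(samples$delta_qaly),
                  prob_ce = mean(samples$nmb > 0),
                  wtp = wtp, n = n, n_failed = length(failures))
  structure(list(samples = samples, params = draws[ok, , drop = FALSE],
                 summary = summary, failures = failures),
            class = "psa_result")
}

# vectorized nmb used internally
nmb_vec <- function(delta_cost, delta_qaly, wtp) wtp * delta_qaly - delta_cost

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<psa_result> %d draws (%d failed)\n",
                     "  mean dCost %.2f, mean dQALY %.4f, ICER %.2f RMB/QALY\n",
                     "  P(cost-effective at WTP %.0f) = %.3f\n"),
              s$n, s$n_failed, s$mean_delta_cost, s$mean_delta_qaly, s$icer,
              s$wtp, s$prob_ce))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each threshold `lambda` on the grid, the fraction of PSA draws with
#' `lambda * delta_qaly - delta_cost > 0`.
#'
#' @param samples A `psa_result` or its `samples` data frame.
#' @param wtp_grid Non-negative thresholds; default 0 to 400,000 RMB in
#'   2,000-RMB steps.
#' @return Data frame: `wtp`, `probability`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 400000, by = 2000)) {
  if (inherits(samples, "psa_result")) samples <- samples$samples
  stopifnot(is.data.frame(samples),
            all(c("delta_cost", "delta_qaly") %in% names(samples)))
  if (!length(wtp_grid)) stop("empty WTP grid")
  if (any(wtp_grid < 0)) stop("WTP grid must be non-negative")
  if (!nrow(samples)) stop("no PSA samples")
  prob <- vapply(wtp_grid, function(l)
    mean(l * samples$delta_qaly - samples$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}
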