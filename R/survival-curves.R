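#' @importFrom stats pexp dexp qexp rexp pweibull dweibull qweibull rweibull
#'   plnorm dlnorm qlnorm rlnorm uniroot optim integrate
NULL

# canonical time unit is months; calendar days convert at this rate
DAYS_PER_MONTH <- 30.4375

#' Parametric survival families supported by the model
#'
#' The six families used for extrapolating time-to-progression (TTP),
#' progression-free survival (PFS) and post-progression survival (PPS), in
#' their canonical enumeration order (used as the final tie-break in
#' [select_best()]).
#'
#' @format Character vector of family names.
#' @export
SURV_FAMILIES <- c("exponential", "weibull", "lognormal", "loglogistic",
                   "gompertz", "gengamma")

# named parameter layout per family (order matters: it is the `params` order)
.family_params <- list(
  exponential = "rate",
  weibull     = c("shape", "scale"),
  lognormal   = c("meanlog", "sdlog"),
  loglogistic = c("shape", "scale"),
  gompertz    = c("shape", "rate"),
  gengamma    = c("mu", "sigma", "Q")
)

# parameters that must be strictly positive, per family
.family_positive <- list(
  exponential = "rate",
  weibull     = c("shape", "scale"),
  lognormal   = "sdlog",
  loglogistic = c("shape", "scale"),
  gompertz    = "rate",          # gompertz shape may be negative
  gengamma    = "sigma"
)

#' Construct a parametric survival curve
#'
#' A `surv_curve` bundles a distribution family tag with its parameter vector;
#' it is evaluable through [surv_prob()], [surv_hazard()],
#' [transition_prob()] and [median_survival()]. Times are in months.
#'
#' Parameter layouts: `exponential(rate)`, `weibull(shape, scale)`,
#' `lognormal(meanlog, sdlog)`, `loglogistic(shape, scale)`,
#' `gompertz(shape, rate)` (shape may be negative), and
#' `gengamma(mu, sigma, Q)` in the location/scale/signed-shape
#' parameterization: for `Q != 0`,
#' `S(t) = 1 - P(gamma, gamma * exp(Q * w))` when `Q > 0` and
#' `S(t) = P(gamma, gamma * exp(Q * w))` when `Q < 0`, with
#' `gamma = Q^-2`, `w = (log t - mu) / sigma` and `P` the regularized lower
#' incomplete gamma function; `Q -> 0` degenerates to the log-normal and
#' `Q = 1` to the Weibull.
#'
#' @param family One of [SURV_FAMILIES].
#' @param params Numeric vector of family parameters, in the order above
#'   (names, if given, are checked).
#' @param time_unit Currently only `"months"`.
#' @return An object of class `surv_curve`.
#' @examples
#' pps <- surv_curve("lognormal", c(meanlog = 3.0448, sdlog = 1.1876))
#' surv_prob(pps, 21)
#' @export
surv_curve <- function(family, params, time_unit = "months") {
  family <- match.arg(family, SURV_FAMILIES)
  time_unit <- match.arg(time_unit, "months")
  expected <- .family_params[[family]]
  if (length(params) != length(expected))
    stop(sprintf("family '%s' takes %d parameter(s): %s", family,
                 length(expected), paste(expected, collapse = ", ")))
  if (!is.null(names(params)) && any(nzchar(names(params))) &&
      !identical(names(params), expected))
    stop(sprintf("parameter names for '%s' must be: %s", family,
                 paste(expected, collapse = ", ")))
  params <- as.numeric(params)
  names(params) <- expected
  if (any(!is.finite(params)))
    stop("survival-curve parameters must be finite")
  pos <- .family_positive[[family]]
  if (any(params[pos] <= 0))
    stop(sprintf("parameter(s) %s must be > 0 for family '%s'",
                 paste(pos[params[pos] <= 0], collapse = ", "), family))
  if (family == "gengamma" && params[["Q"]] == 0)
    stop("gengamma signed shape Q must be nonzero (use lognormal for Q = 0)")
  structure(list(family = family, params = params, time_unit = time_unit),
            class = "surv_curve")
}

#' @export
print.surv_curve <- function(x, ...) {
  cat(sprintf("<surv_curve> %s(%s), time in %s\n", x$family,
              paste(sprintf("%s = %.6g", names(x$params), x$params),
                    collapse = ", "), x$time_unit))
  invisible(x)
}

.check_curve <- function(curve) {
  if (!inherits(curve, "surv_curve"))
    stop("expected a 'surv_curve' object")
  curve
}

# dispatch table into the standard distribution functions (stats / flexsurv)
.dist_fun <- function(curve, what = c("p", "d", "h", "q", "r")) {
  what <- match.arg(what)
  p <- as.list(unname(curve$params))
  fn <- switch(curve$family,
    exponential = list(p = stats::pexp, d = stats::dexp, q = stats::qexp,
                       r = stats::rexp, h = function(x, rate) rep(rate, length(x))),
    weibull     = list(p = stats::pweibull, d = stats::dweibull,
                       q = stats::qweibull, r = stats::rweibull,
                       h = flexsurv::hweibull),
    lognormal   = list(p = stats::plnorm, d = stats::dlnorm, q = stats::qlnorm,
                       r = stats::rlnorm, h = flexsurv::hlnorm),
    loglogistic = list(p = flexsurv::pllogis, d = flexsurv::dllogis,
                       q = flexsurv::qllogis, r = flexsurv::rllogis,
                       h = flexsurv::hllogis),
    gompertz    = list(p = flexsurv::pgompertz, d = flexsurv::dgompertz,
                       q = flexsurv::qgompertz, r = flexsurv::rgompertz,
                       h = flexsurv::hgompertz),
    gengamma    = list(p = flexsurv::pgengamma, d = flexsurv::dgengamma,
                       q = flexsurv::qgengamma, r = flexsurv::rgengamma,
                       h = flexsurv::hgengamma)
  )[[what]]
  function(x, ...) do.call(fn, c(list(x), p, list(...)))
}

#' Survival probability S(t)
#'
#' @param curve A [surv_curve()].
#' @param t Time(s) in months, `t >= 0`.
#' @return `S(t)` in `[0, 1]`; `S(0) = 1` for every family.
#' @export
surv_prob <- function(curve, t) {
  .check_curve(curve)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0")
  s <- .dist_fun(curve, "p")(t, lower.tail = FALSE)
  pmin(pmax(s, 0), 1)
}

#' Density f(t)
#' @inheritParams surv_prob
#' @return Density values, per month.
#' @export
surv_density <- function(curve, t) {
  .check_curve(curve)
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  .dist_fun(curve, "d")(t)
}

#' Hazard rate h(t) = f(t) / S(t)
#'
#' @inheritParams surv_prob
#' @param t Time(s) in months, `t > 0` with `S(t) > 0`.
#' @return Hazard in events per month, `>= 0`.
#' @export
surv_hazard <- function(curve, t) {
  .check_curve(curve)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("hazard requires t > 0")
  s <- surv_prob(curve, t)
  if (any(s <= .Machine$double.xmin))
    stop("hazard undefined where S(t) = 0 within numerical tolerance")
  pmax(.dist_fun(curve, "h")(t), 0)
}

#' Conditional per-cycle transition probability
#'
#' Probability of experiencing the curve's event during `(t0, t1]` given
#' event-free survival to `t0`: `1 - S(t1) / S(t0)`. This is the quantity the
#' cohort engine applies cycle by cycle (exit from the progression-free state
#' from the PFS curve, progression from the TTP curve, post-progression death
#' from the PPS curve on the time-since-progression clock).
#'
#' @param curve A [surv_curve()].
#' @param t0,t1 Interval endpoints in months, `0 <= t0 < t1`.
#' @return Probability in `[0, 1]`. If `S(t0)` underflows to 0, returns 1 with
#'   a warning (the cohort is already extinct on this curve).
#' @export
transition_prob <- function(curve, t0, t1) {
  .check_curve(curve)
  if (any(!is.finite(c(t0, t1))) || any(t0 < 0))
    stop("t0 must be finite and >= 0")
  if (any(t1 <= t0)) stop("t1 must be > t0")
  s0 <- surv_prob(curve, t0)
  s1 <- surv_prob(curve, t1)
  out <- ifelse(s0 <= .Machine$double.xmin, NA_real_, 1 - s1 / s0)
  if (anyNA(out)) {
    warning("S(t0) = 0 within numerical tolerance; returning 1 by convention")
    out[is.na(out)] <- 1
  }
  pmin(pmax(out, 0), 1)
}

#' Median survival time
#'
#' Root of `S(t) = 0.5`. Closed forms are used for the exponential
#' (`log(2) / rate`) and log-normal (`exp(meanlog)`); other families are
#' solved by bracketed root-finding to relative tolerance 1e-8.
#'
#' @param curve A [surv_curve()].
#' @return Median in months, or `NA_real_` (with a warning) if `S` never
#'   reaches 0.5 on `(0, 1e6]` months.
#' @export
median_survival <- function(curve) {
  .check_curve(curve)
  p <- curve$params
  switch(curve$family,
    exponential = log(2) / p[["rate"]],
    lognormal   = exp(p[["meanlog"]]),
    {
      upper <- 1e6
      if (surv_prob(curve, upper) > 0.5) {
        warning("median not reached on (0, 1e6] months")
        return(NA_real_)
      }
      root <- uniroot(function(t) surv_prob(curve, t) - 0.5,
                      lower = 1e-12, upper = upper, tol = 1e-12)
      # polish to relative tolerance
      uniroot(function(t) surv_prob(curve, t) - 0.5,
              lower = root$root * (1 - 1e-4), upper = root$root * (1 + 1e-4),
              tol = root$root * 1e-10)$root
    })
}

#' Draw random variates from a survival curve
#'
#' @param n Number of draws.
#' @param curve A [surv_curve()].
#' @return Numeric vector of event times in months.
#' @export
surv_rand <- function(n, curve) {
  .check_curve(curve)
  .dist_fun(curve, "r")(n)
}
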