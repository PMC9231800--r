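#' @importFrom survival Surv
NULL

# flexsurv distribution tags for our family names
.flexsurv_dist <- c(exponential = "exp", weibull = "weibull",
                    lognormal = "lnorm", loglogistic = "llogis",
                    gompertz = "gompertz", gengamma = "gengamma")

.check_ipd <- function(data) {
  if (!is.data.frame(data) || !all(c("time", "event") %in% names(data)))
    stop("IPD must be a data frame with columns 'time' and 'event'")
  if (any(!is.finite(data$time)) || any(data$time < 0))
    stop("times must be finite and >= 0")
  if (!all(data$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (observed)")
  invisible(data)
}

# signature used by select_best to verify fits come from identical data
.data_signature <- function(data) {
  c(n = nrow(data), events = sum(data$event), total_time = sum(data$time))
}

#' Fit a parametric survival family to right-censored data
#'
#' Maximizes the right-censored log-likelihood
#' `sum(event * log f(t) + (1 - event) * log S(t))` by multi-start
#' quasi-Newton optimization (positive parameters on the log scale), via
#' [flexsurv::flexsurvreg()]. The default starting values are perturbed by
#' fixed factors and the best converged optimum is kept.
#'
#' @param data Data frame with columns `time` (months, `>= 0`) and `event`
#'   (1 = event observed, 0 = right-censored). At least 10 records with at
#'   least one event.
#' @param family One of [SURV_FAMILIES].
#' @return An object of class `surv_fit`: `curve` (the fitted
#'   [surv_curve()]), `loglik`, `aic` (`2p - 2 loglik`),
#'   `bic` (`p log(n) - 2 loglik`), `n`, `se` (delta-method standard errors on
#'   the natural parameter scale), `vcov` (covariance on the optimizer's
#'   transformed scale, may be `NULL` if the curvature estimate fails).
#' @export
fit_parametric <- function(data, family) {
  family <- match.arg(family, SURV_FAMILIES)
  .check_ipd(data)
  if (nrow(data) < 10) stop("need at least 10 records")
  if (sum(data$event) < 1) stop("all records censored: cannot fit")
  dist <- .flexsurv_dist[[family]]
  # flexsurvreg rejects exact zeros; nudge to half the smallest positive time
  if (any(data$time == 0)) {
    eps <- min(data$time[data$time > 0], 1) / 2
    data$time[data$time == 0] <- eps
  }
  quiet_fit <- function(inits = NULL) {
    tryCatch(
      withCallingHandlers({
        if (is.null(inits)) {
          flexsurv::flexsurvreg(Surv(time, event) ~ 1, data = data, dist = dist)
        } else {
          flexsurv::flexsurvreg(Surv(time, event) ~ 1, data = data, dist = dist,
                                inits = inits)
        }
      }, warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
  }
  base_fit <- quiet_fit()
  fits <- list()
  if (!is.null(base_fit)) fits[[1L]] <- base_fit
  if (!is.null(base_fit)) {
    for (mult in c(0.8, 1.25, 0.5, 2)) {
      f <- quiet_fit(base_fit$res[, "est"] * mult)
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
  }
  if (!length(fits))
    stop(sprintf("fit_parametric: no start converged for family '%s'", family))
  f <- fits[[which.max(vapply(fits, function(x) x$loglik, numeric(1)))]]
  est <- f$res[, "est"]
  p <- length(est)
  n <- nrow(data)
  curve <- surv_curve(family, unname(est))
  vc <- tryCatch(stats::vcov(f), error = function(e) NULL)
  structure(list(curve = curve, loglik = f$loglik,
                 aic = 2 * p - 2 * f$loglik,
                 bic = p * log(n) - 2 * f$loglik,
                 n = n, se = f$res[, "se"], vcov = vc,
                 data_signature = .data_signature(data)),
            class = "surv_fit")
}

#' @export
print.surv_fit <- function(x, ...) {
  cat(sprintf("<surv_fit> %s, n = %d, loglik = %.3f, AIC = %.2f, BIC = %.2f\n",
              x$curve$family, x$n, x$loglik, x$aic, x$bic))
  print(data.frame(est = x$curve$params, se = x$se))
  invisible(x)
}

#' Select the best fit by information criterion
#'
#' Ties are broken deterministically: fewer parameters first, then the
#' family's position in [SURV_FAMILIES].
#'
#' @param fits List of [fit_parametric()] results, all on identical data.
#' @param criterion `"AIC"` or `"BIC"`.
#' @return The selected `surv_fit`.
#' @export
select_best <- function(fits, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (!length(fits)) stop("empty fit list")
  stopifnot(all(vapply(fits, inherits, logical(1), "surv_fit")))
  sigs <- vapply(fits, function(f) f$data_signature, numeric(3))
  if (any(apply(sigs, 1, function(r) max(abs(r - r[1]))) > 1e-8))
    stop("fits were computed on different data")
  crit <- vapply(fits, function(f) if (criterion == "AIC") f$aic else f$bic,
                 numeric(1))
  npar <- vapply(fits, function(f) length(f$curve$params), numeric(1))
  fam  <- vapply(fits, function(f) match(f$curve$family, SURV_FAMILIES),
                 numeric(1))
  fits[[order(crit, npar, fam)[1]]]
}

#' Read individual patient data from CSV
#'
#' Expects a header with columns `time` (months) and `event` (0/1).
#'
#' @param path CSV file path.
#' @return Data frame with `time`, `event`.
#' @export
read_ipd <- function(path) {
  if (!file.exists(path)) stop("IPD file not found: ", path)
  d <- utils::read.csv(path)
  .check_ipd(d[c("time", "event")])
}

#' Write individual patient data to CSV
#'
#' @param data Data frame with `time`, `event`.
#' @param path Output path.
#' @export
write_ipd <- function(data, path) {
  .check_ipd(data)
  utils::write.csv(data[c("time", "event")], path, row.names = FALSE)
  invisible(path)
}
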