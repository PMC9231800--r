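#' Compare two arms: increments, ICER, decision at a WTP threshold
#'
#' The ICER is defined as `delta_cost / delta_qaly` when `delta_qaly > 0`;
#' `"dominant"` labels lower cost with higher QALYs, `"dominated"` higher
#' cost with lower QALYs; an incremental QALY of (numerically) zero with a
#' nonzero cost difference yields `"undefined ICER"` with no division.
#'
#' @param intervention,comparator Lists with elements `econ` (an
#'   `econ_result`) and `cost` (a `cost_result`), e.g. the intervention and
#'   best-supportive-care arms.
#' @param wtp Willingness-to-pay threshold in RMB/QALY; the default is three
#'   times 2019 Chinese GDP per capita.
#' @return Object of class `cea_comparison`: `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `icer` (number or `NA`), `label`, `cost_effective`, `nmb`,
#'   `wtp`.
#' @export
compare_arms <- function(intervention, comparator, wtp = 212676) {
  for (a in list(intervention, comparator)) {
    stopifnot(inherits(a$econ, "econ_result"), inherits(a$cost, "cost_result"))
  }
  if (abs(intervention$econ$discount_rate - comparator$econ$discount_rate) >
      1e-12)
    stop("arms must be computed at the same discount rate")
  dc <- intervention$cost$total - comparator$cost$total
  dq <- intervention$econ$qaly_total - comparator$econ$qaly_total
  dl <- intervention$econ$ly_total - comparator$econ$ly_total
  icer <- NA_real_
  if (abs(dq) < 1e-9) {
    label <- if (abs(dc) < 1e-9) "equivalent" else "undefined ICER"
  } else if (dq > 0 && dc < 0) {
    label <- "dominant"
  } else if (dq < 0 && dc > 0) {
    label <- "dominated"
  } else if (dq > 0) {
    icer <- dc / dq
    label <- "ICER"
  } else {
    # dq < 0, dc < 0: savings per QALY forgone (south-west quadrant)
    icer <- dc / dq
    label <- "ICER (south-west)"
  }
  ce <- label == "dominant" ||
    (label == "ICER" && !is.na(icer) && icer <= wtp)
  structure(list(delta_cost = dc, delta_qaly = dq, delta_ly = dl,
                 icer = icer, label = label, cost_effective = ce,
                 nmb = nmb(dc, dq, wtp), wtp = wtp),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf(paste0("<cea_comparison> dCost %.2f RMB, dQALY %.4f, dLY %.4f\n",
                     "  %s%s; NMB at WTP %.0f: %.2f RMB; cost-effective: %s\n"),
              x$delta_cost, x$delta_qaly, x$delta_ly, x$label,
              if (!is.na(x$icer)) sprintf(" = %.2f RMB/QALY", x$icer) else "",
              x$wtp, x$nmb, x$cost_effective))
  invisible(x)
}

#' Convert a comparison to a one-row data frame
#' @param x A `cea_comparison`.
#' @param ... Unused.
#' @return One-row data frame.
#' @export
as.data.frame.cea_comparison <- function(x, ...) {
  data.frame(delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
             delta_ly = x$delta_ly, icer = x$icer, label = x$label,
             cost_effective = x$cost_effective, nmb = x$nmb, wtp = x$wtp)
}

#' Net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`: positive exactly when the intervention is
#' cost-effective at the threshold.
#'
#' @param delta_cost Incremental cost.
#' @param delta_qaly Incremental QALYs.
#' @param wtp Willingness-to-pay per QALY.
#' @return NMB in currency units.
#' @export
nmb <- function(delta_cost, delta_qaly, wtp) {
  stopifnot(is.finite(delta_cost), is.finite(delta_qaly), is.finite(wtp))
  wtp * delta_qaly - delta_cost
}
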