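#' Net monetary benefit
#'
#' `NMB = WTP x delta_QALYs - delta_cost`. A positive NMB means the
#' strategy is cost-effective at that willingness-to-pay threshold; the
#' linear form avoids the awkward statistical properties of the ICER ratio
#' when summarising Monte-Carlo draws. Vectorised over all arguments.
#'
#' @param delta_cost Incremental cost (AUD), specialist minus comparator.
#' @param delta_qalys Incremental effect (QALYs).
#' @param wtp Willingness to pay per QALY (AUD), >= 0.
#' @return NMB in AUD.
#' @export
#' @examples
#' nmb(-3947, 0.04, 64000)
nmb <- function(delta_cost, delta_qalys, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be non-negative", call. = FALSE)
  wtp * delta_qalys - delta_cost
}

#' Incremental cost-effectiveness ratio with dominance labelling
#'
#' @param delta_cost,delta_qalys Scalar increments (new minus comparator).
#' @return List with `value` (AUD/QALY, `NA` under dominance) and `label`:
#'   `"dominant"` when cheaper and more effective, `"dominated"` when more
#'   expensive and less effective, otherwise the ratio with a
#'   north-east/south-west quadrant label.
#' @export
icer <- function(delta_cost, delta_qalys) {
  if (delta_cost < 0 && delta_qalys > 0) {
    list(value = NA_real_, label = "dominant")
  } else if (delta_cost > 0 && delta_qalys < 0) {
    list(value = NA_real_, label = "dominated")
  } else if (delta_qalys == 0) {
    list(value = NA_real_,
         label = if (delta_cost <= 0) "cost-saving, equal effect"
                 else "costlier, equal effect")
  } else {
    list(value = delta_cost / delta_qalys,
         label = if (delta_qalys > 0) "more effective, costlier"
                 else "less effective, cheaper")
  }
}

#' Probability that the strategy is cost-effective
#'
#' Fraction of PSA draws whose net monetary benefit is non-negative at the
#' given threshold. Draws with NMB exactly zero count as cost-effective
#' (a measure-zero tie convention, documented here for reproducibility).
#'
#' @param psa A [run_psa] result.
#' @param wtp Willingness-to-pay threshold (AUD/QALY).
#' @return Fraction in \[0, 1\].
#' @export
prob_cost_effective <- function(psa, wtp) {
  stopifnot(inherits(psa, "cea_psa"))
  if (psa$n_sims < 1) stop("empty PSA result", call. = FALSE)
  mean(nmb(psa$delta_cost, psa$delta_qalys, wtp) >= 0)
}

#' Cost-effectiveness acceptability curve
#'
#' Evaluates [prob_cost_effective] over a grid of willingness-to-pay
#' thresholds, by default $0 to $100,000 per QALY.
#'
#' @param psa A [run_psa] result.
#' @param wtp_grid Strictly increasing vector of thresholds (AUD/QALY).
#' @return A `cea_ceac` data.frame with columns `wtp` and
#'   `prob_cost_effective`.
#' @export
#' @examples
#' cfg <- default_config()
#' psa <- run_psa(cfg, n_sims = 200, seed = 1)
#' head(ceac(psa))
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 2000)) {
  stopifnot(inherits(psa, "cea_psa"))
  if (length(wtp_grid) < 1 || any(diff(wtp_grid) <= 0)) {
    stop("`wtp_grid` must be strictly increasing", call. = FALSE)
  }
  if (any(wtp_grid < 0)) stop("`wtp_grid` must be non-negative", call. = FALSE)
  prob <- vapply(wtp_grid, function(w) prob_cost_effective(psa, w),
                 numeric(1))
  structure(data.frame(wtp = wtp_grid, prob_cost_effective = prob),
            class = c("cea_ceac", "data.frame"))
}

#' @export
plot.cea_ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$prob_cost_effective, type = "l", lwd = 2,
                 ylim = c(0, 1),
                 xlab = "Willingness to pay (AUD per QALY)",
                 ylab = "Probability cost-effective",
                 main = "Cost-effectiveness acceptability curve", ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
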