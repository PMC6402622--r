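#' Propagate the cohort through the transition matrix
#'
#' Expected-value (cohort-fraction) propagation: row `k` of the returned
#' trace is the state-occupancy distribution after `k` monthly cycles,
#' starting from `init`. The whole cohort starts in the uncomplicated state
#' by default, reflecting enrolment with an active wound.
#'
#' @param tm A 4x4 row-stochastic `transition_matrix`.
#' @param n_cycles Number of cycles to run (12 for the 1-year horizon).
#' @param init Initial occupancy vector summing to 1.
#' @return A `cohort_trace`: `(n_cycles + 1) x 4` matrix of occupancy
#'   fractions, rows labelled `cycle_0 ... cycle_<n>`.
#' @export
run_cohort <- function(tm, n_cycles = 12,
                       init = c(1, 0, 0, 0)) {
  if (!is.matrix(tm) || !all(dim(tm) == .n_states)) {
    stop("`tm` must be a 4x4 matrix", call. = FALSE)
  }
  if (length(init) != ncol(tm)) {
    stop("`init` has length ", length(init), " but the matrix has ",
         ncol(tm), " states", call. = FALSE)
  }
  if (abs(sum(init) - 1) > 1e-9) {
    stop("`init` must sum to 1", call. = FALSE)
  }
  stopifnot(n_cycles >= 1, n_cycles == round(n_cycles))
  occ <- matrix(0, n_cycles + 1, .n_states,
                dimnames = list(paste0("cycle_", 0:n_cycles), wound_states()))
  occ[1, ] <- init
  v <- init
  for (k in seq_len(n_cycles)) {
    v <- as.numeric(v %*% tm)
    occ[k + 1, ] <- v
  }
  structure(occ, class = c("cohort_trace", "matrix", "array"))
}

# cycle weights for each accrual convention; trace has n+1 rows (cycle 0..n)
.accrual_conventions <- c("all_cycles", "end_of_cycle", "start_of_cycle",
                          "half_cycle")

accrual_weights <- function(trace, convention) {
  n <- nrow(trace) - 1L
  switch(convention,
    all_cycles = trace,
    end_of_cycle = trace[1L + seq_len(n), , drop = FALSE],
    start_of_cycle = trace[seq_len(n), , drop = FALSE],
    half_cycle = (trace[seq_len(n), , drop = FALSE] +
                    trace[1L + seq_len(n), , drop = FALSE]) / 2,
    stop("unknown accrual convention: ", convention, call. = FALSE)
  )
}

#' Accrue costs and QALYs over the cohort trace
#'
#' Costs accrue as occupancy times the monthly state cost; QALYs as
#' occupancy times the state utility divided by 12 (monthly cycles, annual
#' utility weights). The dead state contributes nothing to either. The
#' `convention` controls which trace rows accrue:
#' \describe{
#'   \item{`all_cycles`}{every row of the trace, cycle 0 through `n`
#'     (the package default; see the methods vignette)}
#'   \item{`end_of_cycle`}{end-of-cycle membership, cycles 1..n}
#'   \item{`start_of_cycle`}{start-of-cycle membership, cycles 0..n-1}
#'   \item{`half_cycle`}{the mean of adjacent rows (half-cycle correction)}
#' }
#' The `perspective` restricts which payer's costs count: the restricted
#' societal default sums patient out-of-pocket and health-system costs.
#' Excluded components are reported as zero so that
#' `total_cost = oop_cost + health_system_cost` always holds.
#'
#' @param trace A [run_cohort] trace.
#' @param sp The [strategy_params] that generated it.
#' @param perspective One of `"total"`, `"health_system"`,
#'   `"out_of_pocket"`.
#' @param convention Accrual convention, see above.
#' @return A `strategy_outcome`: list with `total_cost`, `oop_cost`,
#'   `health_system_cost` (AUD per patient per year), `total_qalys`,
#'   `trace`, and the convention/perspective used.
#' @export
accrue_outcomes <- function(trace, sp,
                            perspective = c("total", "health_system",
                                            "out_of_pocket"),
                            convention = .accrual_conventions) {
  stopifnot(inherits(sp, "strategy_params"))
  perspective <- match.arg(perspective)
  convention <- match.arg(convention)
  if (!is.matrix(trace) || ncol(trace) != .n_states) {
    stop("`trace` must be an occupancy matrix over the four states",
         call. = FALSE)
  }
  occ <- colSums(accrual_weights(trace, convention))
  oop <- sum(occ * sp$cost_out_of_pocket)
  hs <- sum(occ * sp$cost_health_system)
  qalys <- sum(occ * sp$utilities) / 12
  if (perspective == "health_system") oop <- 0
  if (perspective == "out_of_pocket") hs <- 0
  structure(list(strategy = sp$label,
                 total_cost = oop + hs,
                 oop_cost = oop,
                 health_system_cost = hs,
                 total_qalys = qalys,
                 perspective = perspective,
                 convention = convention,
                 trace = trace),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("%s (%s perspective, %s accrual)\n", x$strategy,
              x$perspective, x$convention))
  cat(sprintf("  cost  %10.0f AUD  (oop %.0f + health system %.0f)\n",
              x$total_cost, x$oop_cost, x$health_system_cost))
  cat(sprintf("  QALYs %10.4f per patient per year\n", x$total_qalys))
  invisible(x)
}

# build the matrix, run 12 cycles and accrue, for one strategy
run_strategy <- function(sp, n_cycles = 12, perspective = "total",
                         convention = "all_cycles") {
  tm <- build_transition_matrix(sp)
  trace <- run_cohort(tm, n_cycles = n_cycles)
  accrue_outcomes(trace, sp, perspective = perspective,
                  convention = convention)
}

#' Deterministic evaluation of both strategies
#'
#' Runs the cohort model at the fixed (mean) input values for usual care
#' and the specialist clinic, and derives the incremental results: cost
#' difference, QALY difference, ICER and net monetary benefit at the
#' configured willingness-to-pay threshold. Increments are specialist
#' minus usual care throughout.
#'
#' @param config A model configuration, see [load_config] /
#'   [default_config].
#' @param perspective Costing perspective override; defaults to the
#'   config's setting.
#' @param convention Accrual convention override; defaults to the config's
#'   setting.
#' @return An object of class `cea_deterministic` with the two
#'   `strategy_outcome`s and the incremental metrics.
#' @export
#' @examples
#' det <- run_deterministic(default_config())
#' det
run_deterministic <- function(config, perspective = NULL,
                              convention = NULL) {
  config <- validate_config(config)
  if (is.null(perspective)) perspective <- config$settings$perspective
  if (is.null(convention)) convention <- config$settings$accrual_convention
  n_cycles <- config$settings$cycles
  sp_u <- strategy_params_from_config(config, "usual_care")
  sp_s <- strategy_params_from_config(config, "specialist_clinic")
  usual <- run_strategy(sp_u, n_cycles, perspective, convention)
  specialist <- run_strategy(sp_s, n_cycles, perspective, convention)
  dc <- specialist$total_cost - usual$total_cost
  de <- specialist$total_qalys - usual$total_qalys
  wtp <- config$settings$wtp_threshold
  structure(list(usual = usual, specialist = specialist,
                 delta_cost = dc, delta_qalys = de,
                 icer = icer(dc, de),
                 nmb = nmb(dc, de, wtp),
                 wtp = wtp, perspective = perspective,
                 convention = convention),
            class = "cea_deterministic")
}

#' @export
print.cea_deterministic <- function(x, ...) {
  fmt_aud <- function(v) formatC(round(v), format = "d", big.mark = ",")
  cat(sprintf("Deterministic results (per patient, per year; %s perspective, %s accrual)\n\n",
              x$perspective, x$convention))
  rows <- rbind(
    c("Out of pocket costs", fmt_aud(x$usual$oop_cost),
      fmt_aud(x$specialist$oop_cost)),
    c("Health system costs", fmt_aud(x$usual$health_system_cost),
      fmt_aud(x$specialist$health_system_cost)),
    c("Total costs", fmt_aud(x$usual$total_cost),
      fmt_aud(x$specialist$total_cost)),
    c("Total QALYs", sprintf("%.2f", x$usual$total_qalys),
      sprintf("%.2f", x$specialist$total_qalys)))
  df <- data.frame(rows[, 1], rows[, 2], rows[, 3], check.names = FALSE)
  names(df) <- c(" ", "Usual Care", "Specialist Clinics")
  print(df, row.names = FALSE, right = TRUE)
  cat(sprintf("\nTotal incremental costs:  %s AUD\n", fmt_aud(x$delta_cost)))
  cat(sprintf("Total incremental QALYs:  %.2f\n", x$delta_qalys))
  lab <- x$icer$label
  cat(sprintf("ICER: %s\n",
              if (is.na(x$icer$value)) lab
              else sprintf("%s AUD/QALY (%s)", fmt_aud(x$icer$value), lab)))
  cat(sprintf("Net monetary benefit at WTP %s AUD/QALY: %s AUD\n",
              fmt_aud(x$wtp), fmt_aud(x$nmb)))
  invisible(x)
}

#' @export
summary.cea_deterministic <- function(object, ...) {
  print(object, ...)
}

#' Tidy per-cycle accrual table for audit
#'
#' Long-format table of the trace with per-cycle cost and QALY accruals
#' under the outcome's convention: one row per accrual cycle and state.
#'
#' @param outcome A `strategy_outcome` from [accrue_outcomes].
#' @param sp The matching [strategy_params].
#' @return A data.frame with columns `cycle`, `state`, `occupancy`,
#'   `cost`, `qaly`.
#' @export
trace_accrual_table <- function(outcome, sp) {
  stopifnot(inherits(outcome, "strategy_outcome"),
            inherits(sp, "strategy_params"))
  w <- accrual_weights(outcome$trace, outcome$convention)
  cost_state <- sp$cost_out_of_pocket + sp$cost_health_system
  if (outcome$perspective == "health_system") cost_state <- sp$cost_health_system
  if (outcome$perspective == "out_of_pocket") cost_state <- sp$cost_out_of_pocket
  cyc <- as.integer(sub("cycle_", "", rownames(w)))
  out <- data.frame(
    cycle = rep(cyc, times = .n_states),
    state = rep(wound_states(), each = nrow(w)),
    occupancy = as.vector(w),
    cost = as.vector(sweep(w, 2, cost_state, `*`)),
    qaly = as.vector(sweep(w, 2, sp$utilities / 12, `*`)))
  out[order(out$cycle, match(out$state, wound_states())), ,
      drop = FALSE]
}
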