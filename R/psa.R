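#' Beta distribution from a mean and pseudo-sample size
#'
#' Method-of-moments beta fit used for probabilities and utilities:
#' `alpha = mean * n`, `beta = (1 - mean) * n`, so the distribution's mean
#' equals the stated mean exactly and `n` (the "effective sample size")
#' controls dispersion the way a binomial denominator would.
#'
#' @param mean Mean in (0, 1). A mean of exactly 0 or 1 is degenerate and
#'   rejected; callers treat such parameters as fixed rather than sampled.
#' @param effective_n Positive pseudo-sample size.
#' @return Named numeric vector `c(shape1, shape2)` for [stats::rbeta].
#' @export
#' @examples
#' fit_beta(0.5, 2)      # the uniform distribution
#' fit_beta(0.345, 26)   # specialist 3-month healing, 9/26 healed
fit_beta <- function(mean, effective_n) {
  if (!is.numeric(mean) || length(mean) != 1 || is.na(mean) ||
      mean <= 0 || mean >= 1) {
    stop("`mean` must lie strictly inside (0, 1); a mean of exactly 0 or 1 ",
         "is a degenerate (fixed) parameter", call. = FALSE)
  }
  if (!is.numeric(effective_n) || length(effective_n) != 1 ||
      is.na(effective_n) || effective_n <= 0 || !is.finite(effective_n)) {
    stop("`effective_n` must be a positive finite number", call. = FALSE)
  }
  c(shape1 = mean * effective_n, shape2 = (1 - mean) * effective_n)
}

#' Gamma distribution from a mean and coefficient of variation
#'
#' Method-of-moments gamma fit used for costs, reflecting their right
#' skew: `shape = 1 / cv^2`, `scale = mean * cv^2`, so the mean equals the
#' stated mean exactly and the standard deviation is `mean * cv`.
#'
#' @param mean Positive mean (AUD). A non-positive mean signals a
#'   parameter held fixed (e.g. the dead state's zero cost) and is
#'   rejected here.
#' @param cv Positive coefficient of variation.
#' @return Named numeric vector `c(shape, scale)` for [stats::rgamma].
#' @export
#' @examples
#' fit_gamma(1000, 1)      # exponential with mean 1000
#' fit_gamma(30319, 0.2)   # hospitalised-month cost
fit_gamma <- function(mean, cv) {
  if (!is.numeric(mean) || length(mean) != 1 || is.na(mean) || mean <= 0) {
    stop("`mean` must be positive; non-positive costs are fixed, not sampled",
         call. = FALSE)
  }
  if (!is.numeric(cv) || length(cv) != 1 || is.na(cv) || cv <= 0) {
    stop("`cv` must be positive", call. = FALSE)
  }
  c(shape = 1 / cv^2, scale = mean * cv^2)
}

# n draws from the beta around `mean`; fixed when degenerate or effective_n
# is infinite (the zero-dispersion limit)
draw_beta <- function(n, mean, effective_n) {
  if (mean <= 0 || mean >= 1 || !is.finite(effective_n)) {
    return(rep(mean, n))
  }
  sh <- fit_beta(mean, effective_n)
  stats::rbeta(n, sh[["shape1"]], sh[["shape2"]])
}

# n draws from the gamma around `mean`; fixed when mean is 0 or cv is 0
draw_gamma <- function(n, mean, cv) {
  if (mean <= 0 || cv <= 0) {
    return(rep(mean, n))
  }
  sh <- fit_gamma(mean, cv)
  stats::rgamma(n, shape = sh[["shape"]], scale = sh[["scale"]])
}

# effective_n lookup for a strategy's probability parameter
prob_effective_n <- function(cfg, strategy, param) {
  pen <- cfg$uncertainty$probability_effective_n
  key <- paste(strategy, param, sep = ".")
  if (!is.null(pen[[key]])) pen[[key]] else pen$default
}

# draw the full parameter set for n simulations; returns a list of
# n-vectors in the documented parameter order (see vignette):
# shared (mortality, utilities, hospitalised cost), then usual care, then
# specialist clinic, probabilities before costs within each strategy
draw_parameters <- function(cfg, n) {
  un <- cfg$uncertainty
  d <- list()
  # shared across strategies: same population quantity / same cost source
  pu <- cfg$strategies$usual_care$probabilities
  d$death_all_cause <- draw_beta(n, pu$death_all_cause$value,
                                 prob_effective_n(cfg, "usual_care",
                                                  "death_all_cause"))
  d$death_wound <- draw_beta(n, pu$death_wound$value,
                             prob_effective_n(cfg, "usual_care",
                                              "death_wound"))
  d$u_uncomplicated <- draw_beta(n, cfg$utilities$uncomplicated,
                                 un$utility_effective_n)
  d$u_healed <- draw_beta(n, cfg$utilities$healed, un$utility_effective_n)
  # hospitalised utility preserves the 0.1 decrement construction
  d$u_hospitalised <- pmax(0, d$u_uncomplicated - 0.1)
  hosp <- cfg$strategies$usual_care$costs$hospitalised
  d$cost_hosp_hs <- draw_gamma(n, hospital_cost_health_system(hosp),
                               un$cost_cv)
  d$cost_hosp_oop <- draw_gamma(n, hosp$out_of_pocket, un$cost_cv)
  for (snm in c("usual_care", "specialist_clinic")) {
    pr <- cfg$strategies[[snm]]$probabilities
    cs <- cfg$strategies[[snm]]$costs
    for (pnm in c("complication", "healing", "recurrence")) {
      d[[paste(snm, pnm, sep = ".")]] <-
        draw_beta(n, pr[[pnm]]$value, prob_effective_n(cfg, snm, pnm))
    }
    for (state in c("uncomplicated", "healed")) {
      d[[paste(snm, state, "oop", sep = ".")]] <-
        draw_gamma(n, cs[[state]]$out_of_pocket, un$cost_cv)
      d[[paste(snm, state, "hs", sep = ".")]] <-
        draw_gamma(n, cs[[state]]$health_system, un$cost_cv)
    }
  }
  d
}

# monthly exit-probability feasibility for one strategy's draws
infeasible_draws <- function(cfg, d, snm) {
  pr <- cfg$strategies[[snm]]$probabilities
  m <- function(p, hz) 1 - (1 - p)^(1 / hz)
  mc <- m(d[[paste(snm, "complication", sep = ".")]],
          pr$complication$horizon_months)
  mh <- m(d[[paste(snm, "healing", sep = ".")]], pr$healing$horizon_months)
  mr <- m(d[[paste(snm, "recurrence", sep = ".")]],
          pr$recurrence$horizon_months)
  mda <- m(d$death_all_cause, pr$death_all_cause$horizon_months)
  (mc + mh + mda > 1) | (mr + mda > 1)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: each simulation takes
#' one random draw from every uncertain parameter's distribution
#' (probabilities and utilities: beta; costs: gamma; all means equal to
#' the fixed base-case values), evaluates the full cohort model for both
#' strategies on the same draw of shared parameters (mortality, utilities,
#' hospitalised-month cost), and records the incremental cost and QALY
#' pair, specialist minus usual care.
#'
#' Draws whose monthly exit probabilities for any state sum above 1 are
#' infeasible under the model structure; the offending strategy's
#' probability draws are redrawn for those simulations, the number of
#' affected simulations is recorded, and the run aborts if more than 1% of
#' simulations needed a redraw (a sign the dispersion settings are
#' incompatible with the model).
#'
#' @param config Model configuration.
#' @param n_sims Number of simulations (study value: 10,000).
#' @param seed Integer seed; identical seeds reproduce the draws
#'   bit-for-bit.
#' @param perspective,convention Overrides for the config's costing
#'   perspective and accrual convention.
#' @return An object of class `cea_psa`: paired vectors `delta_cost` and
#'   `delta_qalys` of length `n_sims`, the per-strategy cost/QALY draws,
#'   the seed, redraw count, and a config fingerprint.
#' @export
#' @examples
#' psa <- run_psa(default_config(), n_sims = 100, seed = 1)
#' psa
run_psa <- function(config, n_sims = NULL, seed = NULL,
                    perspective = NULL, convention = NULL) {
  config <- validate_config(config)
  if (is.null(n_sims)) n_sims <- config$settings$n_psa
  if (is.null(seed)) seed <- config$settings$seed
  if (is.null(perspective)) perspective <- config$settings$perspective
  if (is.null(convention)) convention <- config$settings$accrual_convention
  stopifnot(n_sims >= 1, n_sims == round(n_sims))
  n_cycles <- config$settings$cycles

  set.seed(seed)
  d <- draw_parameters(config, n_sims)

  # redraw infeasible simulations (strategy-specific probabilities only;
  # shared draws are kept so pairing is preserved)
  n_redrawn <- 0L
  for (snm in c("usual_care", "specialist_clinic")) {
    bad <- which(infeasible_draws(config, d, snm))
    redrawn <- unique(bad)
    tries <- 0L
    while (length(bad) > 0 && tries < 100L) {
      pr <- config$strategies[[snm]]$probabilities
      for (pnm in c("complication", "healing", "recurrence")) {
        key <- paste(snm, pnm, sep = ".")
        d[[key]][bad] <- draw_beta(length(bad), pr[[pnm]]$value,
                                   prob_effective_n(config, snm, pnm))
      }
      bad <- bad[infeasible_draws(config, d, snm)[bad]]
      tries <- tries + 1L
    }
    if (length(bad) > 0) {
      stop("could not find feasible draws for strategy ", snm, call. = FALSE)
    }
    n_redrawn <- n_redrawn + length(redrawn)
  }
  if (n_redrawn > 0.01 * n_sims) {
    stop(sprintf(
      "%d of %d simulations (%.1f%%) required redraws; dispersion settings ",
      n_redrawn, n_sims, 100 * n_redrawn / n_sims),
      "are incompatible with the model structure", call. = FALSE)
  }

  out <- list(usual_care = NULL, specialist_clinic = NULL)
  for (snm in names(out)) {
    pr <- config$strategies[[snm]]$probabilities
    m <- function(p, hz) 1 - (1 - p)^(1 / hz)
    mc <- m(d[[paste(snm, "complication", sep = ".")]],
            pr$complication$horizon_months)
    mh <- m(d[[paste(snm, "healing", sep = ".")]],
            pr$healing$horizon_months)
    mr <- m(d[[paste(snm, "recurrence", sep = ".")]],
            pr$recurrence$horizon_months)
    mda <- m(d$death_all_cause, pr$death_all_cause$horizon_months)
    mdw <- m(d$death_wound, pr$death_wound$horizon_months)

    oop <- cbind(d[[paste(snm, "uncomplicated", "oop", sep = ".")]],
                 d$cost_hosp_oop,
                 d[[paste(snm, "healed", "oop", sep = ".")]], 0)
    hs <- cbind(d[[paste(snm, "uncomplicated", "hs", sep = ".")]],
                d$cost_hosp_hs,
                d[[paste(snm, "healed", "hs", sep = ".")]], 0)
    if (perspective == "health_system") oop <- oop * 0
    if (perspective == "out_of_pocket") hs <- hs * 0
    cost_state <- oop + hs
    util_state <- cbind(d$u_uncomplicated, d$u_hospitalised, d$u_healed, 0)

    # vectorised propagation: occupancy columns across all sims at once
    o_u <- rep(1, n_sims); o_c <- o_h <- o_d <- rep(0, n_sims)
    occ_u <- o_u; occ_c <- o_c; occ_h <- o_h  # cycle-0 row
    wt0 <- switch(convention, all_cycles = 1, end_of_cycle = 0,
                  start_of_cycle = 1, half_cycle = 0.5)
    acc_u <- wt0 * occ_u; acc_c <- wt0 * occ_c; acc_h <- wt0 * occ_h
    for (k in seq_len(n_cycles)) {
      n_u <- o_u * (1 - mc - mh - mda) + o_c * (1 - mdw) + o_h * mr
      n_c <- o_u * mc
      n_h <- o_u * mh + o_h * (1 - mr - mda)
      n_d <- o_d + o_u * mda + o_c * mdw + o_h * mda
      wt <- switch(convention,
                   all_cycles = 1,
                   end_of_cycle = 1,
                   start_of_cycle = if (k < n_cycles) 1 else 0,
                   half_cycle = if (k < n_cycles) 1 else 0.5)
      # start_of_cycle/half_cycle weight rows 0..n-1 (plus half of row n)
      if (convention %in% c("start_of_cycle", "half_cycle")) {
        acc_u <- acc_u + wt * n_u
        acc_c <- acc_c + wt * n_c
        acc_h <- acc_h + wt * n_h
      } else {
        acc_u <- acc_u + n_u
        acc_c <- acc_c + n_c
        acc_h <- acc_h + n_h
      }
      o_u <- n_u; o_c <- n_c; o_h <- n_h; o_d <- n_d
    }
    cost <- acc_u * cost_state[, 1] + acc_c * cost_state[, 2] +
      acc_h * cost_state[, 3]
    qalys <- (acc_u * util_state[, 1] + acc_c * util_state[, 2] +
                acc_h * util_state[, 3]) / 12
    out[[snm]] <- list(cost = cost, qalys = qalys)
  }

  structure(list(
    n_sims = as.integer(n_sims),
    seed = as.integer(seed),
    delta_cost = out$specialist_clinic$cost - out$usual_care$cost,
    delta_qalys = out$specialist_clinic$qalys - out$usual_care$qalys,
    usual_cost = out$usual_care$cost,
    usual_qalys = out$usual_care$qalys,
    specialist_cost = out$specialist_clinic$cost,
    specialist_qalys = out$specialist_clinic$qalys,
    wtp = config$settings$wtp_threshold,
    perspective = perspective,
    convention = convention,
    n_redrawn = n_redrawn,
    fingerprint = config_fingerprint(config)),
    class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("PSA: %d simulations (seed %d, %s perspective, %s accrual)\n",
              x$n_sims, x$seed, x$perspective, x$convention))
  cat(sprintf("  mean incremental cost:  %10.0f AUD\n", mean(x$delta_cost)))
  cat(sprintf("  mean incremental QALYs: %10.4f\n", mean(x$delta_qalys)))
  cat(sprintf("  mean NMB at WTP %0.f:   %10.0f AUD\n", x$wtp,
              mean(nmb(x$delta_cost, x$delta_qalys, x$wtp))))
  cat(sprintf("  probability cost-effective: %.1f%%\n",
              100 * prob_cost_effective(x, x$wtp)))
  if (x$n_redrawn > 0) {
    cat(sprintf("  %d simulation(s) required feasibility redraws\n",
                x$n_redrawn))
  }
  invisible(x)
}

#' @export
plot.cea_psa <- function(x, ...) {
  graphics::plot(x$delta_qalys, x$delta_cost, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.3),
                 xlab = "Incremental QALYs",
                 ylab = "Incremental cost (AUD)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  graphics::abline(a = 0, b = x$wtp, col = "firebrick", lty = 2)
  invisible(x)
}

#' Export PSA draws as a data.frame
#'
#' @param psa A [run_psa] result.
#' @return data.frame with `sim_id`, `delta_cost`, `delta_qalys`.
#' @export
psa_draws <- function(psa) {
  stopifnot(inherits(psa, "cea_psa"))
  data.frame(sim_id = seq_len(psa$n_sims),
             delta_cost = psa$delta_cost,
             delta_qalys = psa$delta_qalys)
}
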