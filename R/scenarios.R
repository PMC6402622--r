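#' Scenario identifiers
#'
#' The four alternate scenarios examined alongside the baseline:
#' \describe{
#'   \item{`baseline`}{the configuration unchanged}
#'   \item{`health_system_only`}{only health-system costs counted; patient
#'     out-of-pocket costs excluded}
#'   \item{`oop_only`}{only patient out-of-pocket costs counted}
#'   \item{`low_bed_price`}{the $800/day accounting valuation of a ward
#'     bed replaced by a lower, decision-maker-supplied willingness to pay
#'     for freed bed capacity (no default: the replacement price is a
#'     required input)}
#'   \item{`altered_healing`}{the specialist clinic's 3-month healing
#'     probability set to the previously published estimate 0.587 instead
#'     of the study-cohort estimate 0.345}
#' }
#'
#' @return Character vector of scenario ids.
#' @export
scenario_ids <- function() {
  c("baseline", "health_system_only", "oop_only", "low_bed_price",
    "altered_healing")
}

#' Apply a scenario to a configuration
#'
#' Declarative transformation of the base configuration: each scenario
#' overrides a documented, sparse set of config paths and leaves
#' everything else untouched. Applying `baseline` returns the
#' configuration unchanged, bit for bit.
#'
#' @param config Base configuration.
#' @param id Scenario id, see [scenario_ids].
#' @param bed_day_price Replacement ward-bed price per day (AUD),
#'   required by (and only by) `low_bed_price`.
#' @return The transformed configuration.
#' @export
#' @examples
#' cfg <- apply_scenario(default_config(), "altered_healing")
#' cfg$strategies$specialist_clinic$probabilities$healing$value
apply_scenario <- function(config, id, bed_day_price = NULL) {
  config <- validate_config(config)
  if (!id %in% scenario_ids()) {
    stop("unknown scenario id: ", id, call. = FALSE)
  }
  if (!is.null(bed_day_price) && id != "low_bed_price") {
    stop("`bed_day_price` only applies to the low_bed_price scenario",
         call. = FALSE)
  }
  out <- switch(id,
    baseline = config,
    health_system_only = {
      config$settings$perspective <- "health_system"
      config
    },
    oop_only = {
      config$settings$perspective <- "out_of_pocket"
      config
    },
    low_bed_price = {
      if (is.null(bed_day_price)) {
        stop("the low_bed_price scenario requires `bed_day_price`; ",
             "no default replacement price is defined", call. = FALSE)
      }
      check_number(bed_day_price, "bed_day_price", min = 0)
      for (snm in names(config$strategies)) {
        config$strategies[[snm]]$costs$hospitalised$bed_day_price <-
          bed_day_price
      }
      config
    },
    altered_healing = {
      config$strategies$specialist_clinic$probabilities$healing <-
        list(value = 0.587, horizon_months = 3L)
      config
    })
  validate_config(out)
}

#' Run the deterministic and probabilistic pipeline for every scenario
#'
#' Applies each scenario to the base configuration and runs the full
#' pipeline with the same seed (paired comparisons across scenarios), one
#' summary row per scenario: mean net monetary benefit over the PSA
#' draws, its range, the optimal strategy (the sign of the mean NMB), and
#' the probability that the specialist clinic is cost-effective at the
#' configured threshold.
#'
#' The `low_bed_price` scenario is included only when `bed_day_price` is
#' supplied, since no default replacement price exists.
#'
#' @param config Base configuration.
#' @param seed Integer seed shared by all scenarios.
#' @param n_sims Simulations per scenario (defaults to the config's
#'   `n_psa`).
#' @param bed_day_price Optional ward-bed price enabling `low_bed_price`.
#' @return A `cea_scenarios` data.frame with one row per scenario.
#' @export
run_all_scenarios <- function(config, seed = NULL, n_sims = NULL,
                              bed_day_price = NULL) {
  config <- validate_config(config)
  if (is.null(seed)) seed <- config$settings$seed
  if (is.null(n_sims)) n_sims <- config$settings$n_psa
  ids <- scenario_ids()
  if (is.null(bed_day_price)) ids <- setdiff(ids, "low_bed_price")
  rows <- lapply(ids, function(id) {
    cfg <- apply_scenario(config, id,
                          bed_day_price = if (id == "low_bed_price")
                            bed_day_price else NULL)
    det <- run_deterministic(cfg)
    psa <- run_psa(cfg, n_sims = n_sims, seed = seed)
    b <- nmb(psa$delta_cost, psa$delta_qalys, psa$wtp)
    data.frame(
      scenario = id,
      deterministic_nmb = det$nmb,
      mean_nmb = mean(b),
      min_nmb = min(b),
      max_nmb = max(b),
      optimal_strategy = if (mean(b) >= 0) "specialist_clinic"
                         else "usual_care",
      prob_cost_effective = prob_cost_effective(psa, psa$wtp))
  })
  structure(do.call(rbind, rows),
            class = c("cea_scenarios", "data.frame"),
            seed = seed, n_sims = n_sims)
}

#' @export
print.cea_scenarios <- function(x, ...) {
  cat(sprintf("Scenario analyses (%d PSA simulations each, seed %d)\n\n",
              attr(x, "n_sims"), attr(x, "seed")))
  y <- data.frame(
    Scenario = x$scenario,
    `Mean NMB` = sprintf("$%s (%s:%s)",
                         formatC(round(x$mean_nmb), format = "d",
                                 big.mark = ","),
                         formatC(round(x$min_nmb), format = "d",
                                 big.mark = ","),
                         formatC(round(x$max_nmb), format = "d",
                                 big.mark = ",")),
    `Optimal strategy` = x$optimal_strategy,
    `Prob. cost-effective` = sprintf("%.0f%%",
                                     100 * x$prob_cost_effective),
    check.names = FALSE)
  print(y, row.names = FALSE, right = FALSE)
  invisible(x)
}
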