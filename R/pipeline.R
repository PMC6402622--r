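#' Run the full cost-effectiveness analysis
#'
#' Ties the stages together: deterministic evaluation of both strategies,
#' probabilistic sensitivity analysis, the cost-effectiveness
#' acceptability curve, scenario analyses, and a run manifest recording
#' the seed, accrual convention, costing perspective, software version and
#' a fingerprint of the configuration. The deterministic table is
#' independent of the seed; only the PSA-derived outputs vary with it.
#'
#' @param config Model configuration (see [load_config],
#'   [default_config]).
#' @param seed Integer seed for all Monte-Carlo sampling; defaults to the
#'   config's `settings$seed`.
#' @param n_sims PSA simulations; defaults to `settings$n_psa`.
#' @param scenarios Run the scenario analyses as well (default `TRUE`).
#' @param bed_day_price Optional ward-bed price enabling the
#'   `low_bed_price` scenario.
#' @return Object of class `cea_analysis` with components
#'   `deterministic`, `psa`, `ceac`, `scenarios` (or `NULL`) and
#'   `manifest`.
#' @export
#' @examples
#' res <- run_full_analysis(default_config(), seed = 1, n_sims = 200)
#' res$deterministic
run_full_analysis <- function(config, seed = NULL, n_sims = NULL,
                              scenarios = TRUE, bed_day_price = NULL) {
  config <- validate_config(config)
  if (is.null(seed)) seed <- config$settings$seed
  if (is.null(n_sims)) n_sims <- config$settings$n_psa

  det <- run_deterministic(config)
  psa <- run_psa(config, n_sims = n_sims, seed = seed)
  grid <- seq(0, config$settings$wtp_grid_max,
              by = config$settings$wtp_grid_step)
  curve <- ceac(psa, grid)
  scen <- if (scenarios) {
    run_all_scenarios(config, seed = seed, n_sims = n_sims,
                      bed_day_price = bed_day_price)
  }

  manifest <- list(
    package = "woundcea",
    version = as.character(utils::packageVersion("woundcea")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = as.integer(seed),
    n_sims = as.integer(n_sims),
    accrual_convention = config$settings$accrual_convention,
    perspective = config$settings$perspective,
    wtp_threshold = config$settings$wtp_threshold,
    config_fingerprint = config_fingerprint(config),
    currency = "2017 AUD")

  structure(list(config = config, deterministic = det, psa = psa,
                 ceac = curve, scenarios = scen, manifest = manifest),
            class = "cea_analysis")
}

#' @export
print.cea_analysis <- function(x, ...) {
  print(x$deterministic)
  cat("\n")
  print(x$psa)
  if (!is.null(x$scenarios)) {
    cat("\n")
    print(x$scenarios)
  }
  invisible(x)
}

# deterministic results in the published table's layout (long CSV form)
deterministic_table <- function(det) {
  data.frame(
    quantity = c("out_of_pocket_costs", "health_system_costs",
                 "total_costs", "total_qalys"),
    usual_care = c(det$usual$oop_cost, det$usual$health_system_cost,
                   det$usual$total_cost, det$usual$total_qalys),
    specialist_clinic = c(det$specialist$oop_cost,
                          det$specialist$health_system_cost,
                          det$specialist$total_cost,
                          det$specialist$total_qalys),
    incremental = c(det$specialist$oop_cost - det$usual$oop_cost,
                    det$specialist$health_system_cost -
                      det$usual$health_system_cost,
                    det$delta_cost, det$delta_qalys))
}

#' Write an analysis bundle to disk
#'
#' Serialises every output of [run_full_analysis] as plain text under
#' `dir`: the deterministic results table, the per-cycle trace accruals
#' for both strategies, the PSA draws, the CEAC, the scenario summary
#' (when present) — all CSV — and the manifest as JSON. Two runs with the
#' same configuration fingerprint, seed and convention produce identical
#' CSVs.
#'
#' @param analysis A `cea_analysis`.
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_results <- function(analysis, dir) {
  stopifnot(inherits(analysis, "cea_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  det <- analysis$deterministic
  put(deterministic_table(det), "deterministic_table.csv")
  cfg <- analysis$config
  for (snm in c("usual_care", "specialist_clinic")) {
    sp <- strategy_params_from_config(cfg, snm)
    out <- if (snm == "usual_care") det$usual else det$specialist
    put(trace_accrual_table(out, sp), paste0("trace_", snm, ".csv"))
  }
  put(psa_draws(analysis$psa), "psa_draws.csv")
  put(as.data.frame(analysis$ceac), "ceac.csv")
  if (!is.null(analysis$scenarios)) {
    put(as.data.frame(analysis$scenarios), "scenarios.csv")
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(analysis$manifest, mp, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(paths, mp))
}
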