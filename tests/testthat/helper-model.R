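# shared fixtures: all built in code, no files

# default config with a small PSA so routine tests stay fast
test_config <- function(n_psa = 200) {
  cfg <- default_config()
  cfg$settings$n_psa <- n_psa
  cfg
}

# config whose every sampled parameter is held fixed at its mean
zero_dispersion <- function(cfg) {
  pen <- cfg$uncertainty$probability_effective_n
  cfg$uncertainty$probability_effective_n <-
    stats::setNames(as.list(rep(Inf, length(pen))), names(pen))
  cfg$uncertainty$utility_effective_n <- Inf
  cfg$uncertainty$cost_cv <- 0
  cfg
}

# random but structurally valid strategy parameters (for engine oracles)
random_strategy_params <- function() {
  repeat {
    hz <- function() sample(c(1L, 3L, 12L), 1)
    sp <- try(strategy_params(
      label = "random",
      p_complication = horizon_prob(runif(1, 0, 0.9), hz()),
      p_heal = horizon_prob(runif(1, 0, 0.9), hz()),
      p_death_all_cause = horizon_prob(runif(1, 0, 0.3), hz()),
      p_death_wound = horizon_prob(runif(1, 0, 0.3), hz()),
      p_recurrence = horizon_prob(runif(1, 0, 0.9), hz()),
      cost_out_of_pocket = c(uncomplicated = runif(1, 0, 1000),
                             hospitalised = runif(1, 0, 5000),
                             healed = runif(1, 0, 200), dead = 0),
      cost_health_system = c(uncomplicated = runif(1, 0, 1000),
                             hospitalised = runif(1, 0, 40000),
                             healed = runif(1, 0, 200), dead = 0),
      utilities = c(uncomplicated = runif(1, 0.3, 0.8),
                    hospitalised = runif(1, 0.2, 0.7),
                    healed = runif(1, 0.7, 1), dead = 0)),
      silent = TRUE)
    if (!inherits(sp, "try-error")) {
      tm <- try(build_transition_matrix(sp), silent = TRUE)
      if (!inherits(tm, "try-error")) return(sp)
    }
  }
}

# hand-built PSA result from explicit incremental draws
make_psa <- function(delta_cost, delta_qalys, wtp = 64000) {
  structure(list(n_sims = length(delta_cost),
                 seed = 0L,
                 delta_cost = delta_cost,
                 delta_qalys = delta_qalys,
                 wtp = wtp, perspective = "total",
                 convention = "all_cycles",
                 n_redrawn = 0L, fingerprint = "test"),
            class = "cea_psa")
}

# minimal hand-built cohort with the columns estimate_params consumes
hand_cohort <- function(n, healed, hosp_retro = 0, hosp_prosp = 0,
                        deaths = 0, u_baseline = 0.7, u_month3 = 0.9) {
  patients <- data.frame(
    patient_id = seq_len(n),
    age = 72, sex = "female", wound_type = "venous_leg",
    retro_hosp = seq_len(n) <= hosp_retro,
    retro_hosp_month = ifelse(seq_len(n) <= hosp_retro, 6L, NA_integer_),
    prosp_healed = seq_len(n) <= healed,
    prosp_heal_week = ifelse(seq_len(n) <= healed, 4L, NA_integer_),
    prosp_hosp = seq_len(n) <= hosp_prosp,
    prosp_hosp_month = ifelse(seq_len(n) <= hosp_prosp, 2L, NA_integer_),
    prosp_death = seq_len(n) > n - deaths,
    prosp_death_month = ifelse(seq_len(n) > n - deaths, 1L, NA_integer_),
    u_baseline = u_baseline, u_month1 = u_baseline,
    u_month3 = u_month3)
  empty_months <- data.frame(patient_id = integer(0), month = integer(0),
                             state = character(0),
                             cost_out_of_pocket = numeric(0),
                             cost_health_system = numeric(0))
  structure(list(patients = patients, retrospective = empty_months,
                 prospective = empty_months,
                 generating_params = NULL, seed = NULL),
            class = "wound_cohort")
}
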