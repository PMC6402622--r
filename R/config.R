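#' Packaged default model configuration
#'
#' The full set of model inputs for the base-case comparison of specialist
#' wound clinics against usual care: transition probabilities with their
#' native horizons, per-state monthly costs in 2017 AUD split by payer,
#' state utility weights, global run settings (12 monthly cycles,
#' willingness to pay $64,000/QALY, 10,000 PSA simulations) and the
#' dispersion settings used by the probabilistic analysis.
#'
#' The hospitalised-state cost is stored by component — a ward-bed price
#' per day, a length of stay in days, and a non-bed residual — so the
#' bed-price scenario can swap the valuation; the components total
#' $30,319 per hospitalised month. The out-of-pocket/health-system splits
#' of the uncomplicated and healed states are calibrated defaults (see the
#' methods vignette and `scripts/calibrate_splits.R`); the split totals
#' equal the published per-state monthly costs.
#'
#' @return A validated configuration list with components `settings`,
#'   `strategies` (`usual_care`, `specialist_clinic`), `utilities` and
#'   `uncertainty`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$strategies$usual_care$probabilities$complication
default_config <- function() {
  probs <- function(compl, compl_h, heal, heal_h, rec) {
    list(
      complication = list(value = compl, horizon_months = compl_h),
      healing = list(value = heal, horizon_months = heal_h),
      death_all_cause = list(value = 0.016, horizon_months = 12),
      death_wound = list(value = 0.024, horizon_months = 12),
      recurrence = list(value = rec, horizon_months = 12))
  }
  hosp_cost <- list(out_of_pocket = 0, bed_day_price = 800, bed_days = 30,
                    non_bed_health_system = 6319)
  cfg <- list(
    settings = list(
      cycles = 12L,
      cycle_length_months = 1L,
      wtp_threshold = 64000,
      n_psa = 10000L,
      seed = 42L,
      accrual_convention = "all_cycles",
      perspective = "total",
      wtp_grid_max = 100000,
      wtp_grid_step = 2000),
    strategies = list(
      usual_care = list(
        label = "Usual care",
        probabilities = probs(0.379, 12L, 0.228, 3L, 0.557),
        costs = list(
          uncomplicated = list(out_of_pocket = 215, health_system = 306),
          hospitalised = hosp_cost,
          healed = list(out_of_pocket = 34, health_system = 34),
          dead = list(out_of_pocket = 0, health_system = 0))),
      specialist_clinic = list(
        label = "Specialist clinics",
        probabilities = probs(0.034, 3L, 0.345, 3L, 0.222),
        costs = list(
          uncomplicated = list(out_of_pocket = 678, health_system = 491),
          hospitalised = hosp_cost,
          healed = list(out_of_pocket = 42, health_system = 42),
          dead = list(out_of_pocket = 0, health_system = 0)))),
    utilities = list(uncomplicated = 0.69, hospitalised = 0.59,
                     healed = 0.89, dead = 0),
    uncertainty = list(
      probability_effective_n = list(
        default = 100,
        usual_care.complication = 29,
        specialist_clinic.complication = 29,
        specialist_clinic.healing = 26),
      utility_effective_n = 100,
      cost_cv = 0.2))
  validate_config(cfg)
}

#' Path to the packaged default configuration file
#'
#' @return Path to the installed `default_config.json`.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.json", package = "woundcea",
              mustWork = TRUE)
}

#' Load and validate a model configuration
#'
#' Reads a JSON configuration and validates it against the model schema.
#' Validation rejects rather than repairs: missing required keys,
#' unrecognised keys, and out-of-range values each raise an error naming
#' the offending config path.
#'
#' @param path Path to a JSON configuration file.
#' @return The validated configuration list.
#' @export
#' @examples
#' cfg <- load_config(default_config_path())
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  validate_config(cfg)
}

# ---- validation ------------------------------------------------------------

fail_at <- function(path, msg) {
  stop(sprintf("config error at `%s`: %s", path, msg), call. = FALSE)
}

check_keys <- function(x, path, required, optional = character(0)) {
  if (!is.list(x)) fail_at(path, "must be a mapping")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    fail_at(paste(path, missing[1], sep = "."), "required key is missing")
  }
  extra <- setdiff(names(x), c(required, optional))
  if (length(extra) > 0) {
    fail_at(paste(path, extra[1], sep = "."), "unrecognised key")
  }
  invisible(x)
}

check_number <- function(x, path, min = -Inf, max = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    fail_at(path, "must be a single number")
  }
  if (x < min || x > max) {
    fail_at(path, sprintf("value %s outside [%s, %s]", format(x),
                          format(min), format(max)))
  }
  if (integer && x != round(x)) fail_at(path, "must be an integer")
  invisible(as.numeric(x))
}

check_probability_entry <- function(p, path) {
  check_keys(p, path, c("value", "horizon_months"))
  check_number(p$value, paste0(path, ".value"), 0, 1)
  check_number(p$horizon_months, paste0(path, ".horizon_months"),
               min = 1, integer = TRUE)
  invisible(p)
}

#' Validate an in-memory configuration
#'
#' Same checks as [load_config] applied to a configuration list built in
#' code; used internally by every entry point so malformed inputs fail
#' early with a path-qualified message.
#'
#' @param cfg Configuration list.
#' @return `cfg`, invisibly unchanged, if valid.
#' @export
validate_config <- function(cfg) {
  check_keys(cfg, "config",
             c("settings", "strategies", "utilities", "uncertainty"))
  s <- cfg$settings
  check_keys(s, "settings",
             c("cycles", "cycle_length_months", "wtp_threshold", "n_psa",
               "seed", "accrual_convention", "perspective",
               "wtp_grid_max", "wtp_grid_step"))
  check_number(s$cycles, "settings.cycles", min = 1, integer = TRUE)
  check_number(s$cycle_length_months, "settings.cycle_length_months",
               min = 1, max = 1, integer = TRUE)
  check_number(s$wtp_threshold, "settings.wtp_threshold", min = 0)
  check_number(s$n_psa, "settings.n_psa", min = 1, integer = TRUE)
  check_number(s$seed, "settings.seed", integer = TRUE)
  check_number(s$wtp_grid_max, "settings.wtp_grid_max", min = 0)
  check_number(s$wtp_grid_step, "settings.wtp_grid_step", min = 1)
  if (!s$accrual_convention %in% .accrual_conventions) {
    fail_at("settings.accrual_convention",
            paste("must be one of:", paste(.accrual_conventions,
                                           collapse = ", ")))
  }
  if (!s$perspective %in% c("total", "health_system", "out_of_pocket")) {
    fail_at("settings.perspective",
            "must be one of: total, health_system, out_of_pocket")
  }

  check_keys(cfg$strategies, "strategies",
             c("usual_care", "specialist_clinic"))
  for (snm in c("usual_care", "specialist_clinic")) {
    spath <- paste0("strategies.", snm)
    st <- cfg$strategies[[snm]]
    check_keys(st, spath, c("label", "probabilities", "costs"))
    ppath <- paste0(spath, ".probabilities")
    check_keys(st$probabilities, ppath,
               c("complication", "healing", "death_all_cause",
                 "death_wound", "recurrence"))
    for (pnm in names(st$probabilities)) {
      check_probability_entry(st$probabilities[[pnm]],
                              paste(ppath, pnm, sep = "."))
    }
    cpath <- paste0(spath, ".costs")
    check_keys(st$costs, cpath,
               c("uncomplicated", "hospitalised", "healed", "dead"))
    for (state in c("uncomplicated", "healed", "dead")) {
      p <- paste(cpath, state, sep = ".")
      check_keys(st$costs[[state]], p, c("out_of_pocket", "health_system"))
      check_number(st$costs[[state]]$out_of_pocket,
                   paste0(p, ".out_of_pocket"), min = 0)
      check_number(st$costs[[state]]$health_system,
                   paste0(p, ".health_system"), min = 0)
    }
    hp <- paste(cpath, "hospitalised", sep = ".")
    check_keys(st$costs$hospitalised, hp,
               c("out_of_pocket", "bed_day_price", "bed_days",
                 "non_bed_health_system"))
    for (k in names(st$costs$hospitalised)) {
      check_number(st$costs$hospitalised[[k]], paste(hp, k, sep = "."),
                   min = 0)
    }
    if (st$costs$dead$out_of_pocket != 0 ||
        st$costs$dead$health_system != 0) {
      fail_at(paste(cpath, "dead", sep = "."), "dead-state cost must be 0")
    }
  }

  check_keys(cfg$utilities, "utilities",
             c("uncomplicated", "hospitalised", "healed", "dead"))
  for (state in names(cfg$utilities)) {
    check_number(cfg$utilities[[state]], paste0("utilities.", state), 0, 1)
  }
  if (cfg$utilities$dead != 0) {
    fail_at("utilities.dead", "dead-state utility must be 0")
  }

  un <- cfg$uncertainty
  check_keys(un, "uncertainty",
             c("probability_effective_n", "utility_effective_n", "cost_cv"))
  pen <- un$probability_effective_n
  if (!is.list(pen) || !"default" %in% names(pen)) {
    fail_at("uncertainty.probability_effective_n", "needs a `default` key")
  }
  for (k in names(pen)) {
    v <- pen[[k]]
    if (!identical(v, Inf)) {
      check_number(v, paste0("uncertainty.probability_effective_n.", k),
                   min = .Machine$double.eps)
    }
    if (k != "default" &&
        !grepl("^(usual_care|specialist_clinic)\\.(complication|healing|death_all_cause|death_wound|recurrence)$",
               k)) {
      fail_at(paste0("uncertainty.probability_effective_n.", k),
              "must be `default` or `<strategy>.<probability>`")
    }
  }
  if (!identical(un$utility_effective_n, Inf)) {
    check_number(un$utility_effective_n, "uncertainty.utility_effective_n",
                 min = .Machine$double.eps)
  }
  check_number(un$cost_cv, "uncertainty.cost_cv", min = 0)
  invisible(cfg)
}

# ---- derived accessors -----------------------------------------------------

# monthly hospitalised-state cost components (health-system side)
hospital_cost_health_system <- function(cost_hosp) {
  cost_hosp$bed_day_price * cost_hosp$bed_days +
    cost_hosp$non_bed_health_system
}

# per-state monthly cost vectors for one strategy
strategy_cost_vectors <- function(cfg, strategy) {
  costs <- cfg$strategies[[strategy]]$costs
  oop <- c(uncomplicated = costs$uncomplicated$out_of_pocket,
           hospitalised = costs$hospitalised$out_of_pocket,
           healed = costs$healed$out_of_pocket,
           dead = 0)
  hs <- c(uncomplicated = costs$uncomplicated$health_system,
          hospitalised = hospital_cost_health_system(costs$hospitalised),
          healed = costs$healed$health_system,
          dead = 0)
  list(out_of_pocket = oop, health_system = hs)
}

#' Build strategy parameters from a configuration
#'
#' @param cfg A validated configuration.
#' @param strategy `"usual_care"` or `"specialist_clinic"`.
#' @return A [strategy_params] object.
#' @export
strategy_params_from_config <- function(cfg,
                                        strategy = c("usual_care",
                                                     "specialist_clinic")) {
  strategy <- match.arg(strategy)
  pr <- cfg$strategies[[strategy]]$probabilities
  hp <- function(p) horizon_prob(p$value, p$horizon_months)
  cv <- strategy_cost_vectors(cfg, strategy)
  strategy_params(
    label = cfg$strategies[[strategy]]$label,
    p_complication = hp(pr$complication),
    p_heal = hp(pr$healing),
    p_death_all_cause = hp(pr$death_all_cause),
    p_death_wound = hp(pr$death_wound),
    p_recurrence = hp(pr$recurrence),
    cost_out_of_pocket = cv$out_of_pocket,
    cost_health_system = cv$health_system,
    utilities = unlist(cfg$utilities))
}

# ---- fingerprint -----------------------------------------------------------

# 32-bit FNV-1a over the canonical JSON serialisation; cheap content hash
# for run manifests (no cryptographic intent). State kept as a double in
# [0, 2^32); the multiply is split into 16-bit halves to stay within exact
# double-precision integer range.
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)  # xor touches low byte only
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Fingerprint of a configuration
#'
#' Stable short hash of the canonical JSON serialisation, recorded in run
#' manifests so results can be traced to the exact inputs that produced
#' them.
#'
#' @param cfg Configuration list.
#' @return 8-hex-digit character scalar.
#' @export
config_fingerprint <- function(cfg) {
  fnv1a(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)))
}
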