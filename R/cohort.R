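#' Generating parameters for the synthetic cohort
#'
#' The "true" quantities the synthetic-cohort generator simulates from: the
#' model's transition probabilities, state costs and utilities (taken from
#' a model configuration, by default the packaged one) plus cohort
#' composition targets mirroring the study population — mean age 72,
#' 50:50 sex ratio, 73% venous leg ulcers.
#'
#' @param config Model configuration supplying probabilities, costs and
#'   utilities; defaults to [default_config()].
#' @param mean_age,sd_age,age_range Age distribution (normal, truncated).
#' @param p_male Probability of male sex.
#' @param wound_type_probs Named composition fractions over
#'   `venous_leg`, `diabetic_foot`, `other`; must sum to 1.
#' @param utility_effective_n,cost_cv Dispersion of the simulated EQ-5D
#'   indices (beta) and monthly cost items (gamma).
#' @return Object of class `generating_params`.
#' @export
generating_params <- function(config = default_config(),
                              mean_age = 72, sd_age = 13,
                              age_range = c(25, 92),
                              p_male = 0.5,
                              wound_type_probs = c(venous_leg = 0.73,
                                                   diabetic_foot = 0.07,
                                                   other = 0.20),
                              utility_effective_n = 100,
                              cost_cv = 0.2) {
  config <- validate_config(config)
  if (abs(sum(wound_type_probs) - 1) > 1e-9) {
    stop("`wound_type_probs` must sum to 1", call. = FALSE)
  }
  if (!all(c("venous_leg", "diabetic_foot", "other") %in%
             names(wound_type_probs))) {
    stop("`wound_type_probs` must name venous_leg, diabetic_foot, other",
         call. = FALSE)
  }
  pu <- config$strategies$usual_care$probabilities
  ps <- config$strategies$specialist_clinic$probabilities
  structure(list(
    mean_age = mean_age, sd_age = sd_age, age_range = age_range,
    p_male = p_male, wound_type_probs = wound_type_probs,
    p_hosp_usual_annual = pu$complication$value,
    p_hosp_specialist_3m = ps$complication$value,
    p_heal_specialist_3m = ps$healing$value,
    p_death_all_cause_annual = pu$death_all_cause$value,
    u_uncomplicated = config$utilities$uncomplicated,
    u_healed = config$utilities$healed,
    utility_effective_n = utility_effective_n,
    cost_cv = cost_cv,
    costs_usual = strategy_cost_vectors(config, "usual_care"),
    costs_specialist = strategy_cost_vectors(config, "specialist_clinic")),
    class = "generating_params")
}

# monthly cost draws for a vector of states under one strategy's cost map
draw_month_costs <- function(states, cost_vectors, cv) {
  oop <- numeric(length(states))
  hs <- numeric(length(states))
  for (s in unique(states)) {
    idx <- which(states == s)
    oop[idx] <- draw_gamma(length(idx), cost_vectors$out_of_pocket[[s]], cv)
    hs[idx] <- draw_gamma(length(idx), cost_vectors$health_system[[s]], cv)
  }
  list(out_of_pocket = oop, health_system = hs)
}

#' Generate a synthetic patient cohort
#'
#' Simulates patient-level data with the statistical structure the
#' analysis assumes: demographics drawn to match the composition targets
#' in expectation; a 12-month retrospective usual-care history in which
#' each patient is hospitalised with the usual-care annual probability
#' (one-month admission, uniformly placed) and otherwise lives with an
#' uncomplicated wound; and a 3-month prospective specialist follow-up
#' with healing at the specialist 3-month probability (healing week
#' uniform over weeks 1-13), hospitalisation at the specialist 3-month
#' probability, background all-cause mortality, EQ-5D-5L index values at
#' baseline, one month and three months (beta-distributed around the
#' state utilities), and monthly cost items split out-of-pocket vs
#' health-system (gamma-distributed around the state costs).
#'
#' Wound type is a label only — the analysis pools wound types — and
#' recurrence is not observable within either window, mirroring the
#' study's reliance on literature estimates for it.
#'
#' @param n Number of patients (the study cohort had 29).
#' @param gp [generating_params].
#' @param seed Optional integer seed; the same seed reproduces the cohort
#'   exactly.
#' @return Object of class `wound_cohort`: list with data.frames
#'   `patients`, `retrospective` (patient-month), `prospective`
#'   (patient-month), plus the generating parameters and seed.
#' @export
#' @examples
#' coh <- generate_cohort(29, seed = 7)
#' summary(coh)
generate_cohort <- function(n, gp = generating_params(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 ||
      n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  stopifnot(inherits(gp, "generating_params"))
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  age <- round(stats::rnorm(n, gp$mean_age, gp$sd_age))
  age <- pmin(pmax(age, gp$age_range[1]), gp$age_range[2])
  sex <- ifelse(stats::runif(n) < gp$p_male, "male", "female")
  wound_type <- sample(names(gp$wound_type_probs), n, replace = TRUE,
                       prob = gp$wound_type_probs)

  retro_hosp <- stats::runif(n) < gp$p_hosp_usual_annual
  retro_hosp_month <- ifelse(retro_hosp, sample.int(12, n, replace = TRUE),
                             NA_integer_)

  p_death_3m <- 1 - (1 - gp$p_death_all_cause_annual)^(3 / 12)
  prosp_death <- stats::runif(n) < p_death_3m
  prosp_death_month <- ifelse(prosp_death, sample.int(3, n, replace = TRUE),
                              NA_integer_)
  prosp_healed <- !prosp_death & stats::runif(n) < gp$p_heal_specialist_3m
  prosp_heal_week <- ifelse(prosp_healed, sample.int(13, n, replace = TRUE),
                            NA_integer_)
  # month in which healing occurs; healed-state months are those after it
  prosp_heal_month <- ifelse(prosp_healed,
                             pmin(3L, ceiling(prosp_heal_week * 3 / 13)),
                             NA_integer_)
  prosp_hosp <- !prosp_death & stats::runif(n) < gp$p_hosp_specialist_3m
  prosp_hosp_month <- ifelse(prosp_hosp, sample.int(3, n, replace = TRUE),
                             NA_integer_)

  u_baseline <- draw_beta(n, gp$u_uncomplicated, gp$utility_effective_n)
  u_month1 <- draw_beta(n, gp$u_uncomplicated, gp$utility_effective_n)
  u_month3 <- ifelse(prosp_death, NA_real_,
                     ifelse(prosp_healed,
                            draw_beta(n, gp$u_healed,
                                      gp$utility_effective_n),
                            draw_beta(n, gp$u_uncomplicated,
                                      gp$utility_effective_n)))

  patients <- data.frame(
    patient_id = seq_len(n), age = age, sex = sex,
    wound_type = wound_type,
    retro_hosp = retro_hosp, retro_hosp_month = retro_hosp_month,
    prosp_healed = prosp_healed, prosp_heal_week = prosp_heal_week,
    prosp_hosp = prosp_hosp, prosp_hosp_month = prosp_hosp_month,
    prosp_death = prosp_death, prosp_death_month = prosp_death_month,
    u_baseline = u_baseline, u_month1 = u_month1, u_month3 = u_month3)

  # retrospective patient-months: hospitalised in the admission month,
  # uncomplicated otherwise (patients enrolled with active wounds)
  retro <- data.frame(
    patient_id = rep(seq_len(n), each = 12),
    month = rep(1:12, times = n))
  retro$state <- ifelse(
    !is.na(retro_hosp_month[retro$patient_id]) &
      retro$month == retro_hosp_month[retro$patient_id],
    "hospitalised", "uncomplicated")
  rc <- draw_month_costs(retro$state, gp$costs_usual, gp$cost_cv)
  retro$cost_out_of_pocket <- rc$out_of_pocket
  retro$cost_health_system <- rc$health_system

  # prospective patient-months under specialist care
  prosp <- data.frame(
    patient_id = rep(seq_len(n), each = 3),
    month = rep(1:3, times = n))
  pid <- prosp$patient_id
  prosp$state <- "uncomplicated"
  healed_now <- !is.na(prosp_heal_month[pid]) &
    prosp$month > prosp_heal_month[pid]
  prosp$state[healed_now] <- "healed"
  hosp_now <- !is.na(prosp_hosp_month[pid]) &
    prosp$month == prosp_hosp_month[pid]
  prosp$state[hosp_now] <- "hospitalised"
  dead_now <- !is.na(prosp_death_month[pid]) &
    prosp$month >= prosp_death_month[pid]
  prosp$state[dead_now] <- "dead"
  pc <- draw_month_costs(prosp$state, gp$costs_specialist, gp$cost_cv)
  prosp$cost_out_of_pocket <- pc$out_of_pocket
  prosp$cost_health_system <- pc$health_system

  structure(list(patients = patients, retrospective = retro,
                 prospective = prosp, generating_params = gp,
                 seed = seed),
            class = "wound_cohort")
}

#' @export
print.wound_cohort <- function(x, ...) {
  n <- nrow(x$patients)
  cat(sprintf("Synthetic wound cohort: %d patients%s\n", n,
              if (!is.null(x$seed)) sprintf(" (seed %d)", x$seed) else ""))
  cat(sprintf("  mean age %.1f; %.0f%% male; wound types: %s\n",
              mean(x$patients$age),
              100 * mean(x$patients$sex == "male"),
              paste(sprintf("%s %.0f%%", names(table(x$patients$wound_type)),
                            100 * table(x$patients$wound_type) / n),
                    collapse = ", ")))
  cat(sprintf("  retrospective hospitalisations: %d (%.0f%%)\n",
              sum(x$patients$retro_hosp),
              100 * mean(x$patients$retro_hosp)))
  cat(sprintf("  prospective: healed %d (%.0f%%), hospitalised %d, died %d\n",
              sum(x$patients$prosp_healed),
              100 * mean(x$patients$prosp_healed),
              sum(x$patients$prosp_hosp), sum(x$patients$prosp_death)))
  invisible(x)
}

#' @export
summary.wound_cohort <- function(object, ...) print(object, ...)

#' Estimate model inputs from a patient cohort
#'
#' The estimator the model's study-derived inputs come from, applied to
#' (synthetic or real) patient-level data:
#' \itemize{
#'   \item usual-care annual complication probability: retrospective
#'     hospitalised count / n;
#'   \item specialist 3-month complication: prospective hospitalised
#'     count / n;
#'   \item specialist 3-month healing: healed count / at-risk count
#'     (survivors);
#'   \item 3-month all-cause mortality: deaths / n;
#'   \item state utilities: mean baseline EQ-5D index (uncomplicated) and
#'     mean 3-month index among healed patients (healed); hospitalised =
#'     uncomplicated estimate minus the 0.1 decrement;
#'   \item state mean monthly costs: averages of the per-month cost items
#'     by state and strategy.
#' }
#' Quantities not observable in the windows — usual-care healing (a
#' literature input), recurrence and annual wound-related mortality — are
#' reported as `NA` with a note, as are estimates whose at-risk
#' denominator is zero (degenerate cohorts).
#'
#' @param cohort A [generate_cohort] object (or one with the same shape).
#' @param heal_denominator The healing estimator's denominator: survivors
#'   at risk (default) or all enrolled patients. The study's printed
#'   "45% (n = 9)" leaves its denominator ambiguous, so it is a parameter.
#' @return A `wound_param_estimates` data.frame with columns `parameter`,
#'   `strategy`, `estimate`, `se`, `n`, `horizon_months`, `note`.
#' @export
#' @examples
#' est <- estimate_params(generate_cohort(200, seed = 1))
#' est
estimate_params <- function(cohort,
                            heal_denominator = c("at_risk", "all")) {
  heal_denominator <- match.arg(heal_denominator)
  stopifnot(inherits(cohort, "wound_cohort") || is.list(cohort))
  p <- cohort$patients
  if (is.null(p) || nrow(p) == 0) {
    stop("cohort is empty", call. = FALSE)
  }
  n <- nrow(p)
  binom_row <- function(parameter, strategy, k, denom, horizon, note = "") {
    if (denom == 0) {
      return(data.frame(parameter = parameter, strategy = strategy,
                        estimate = NA_real_, se = NA_real_, n = 0,
                        horizon_months = horizon,
                        note = "zero at-risk denominator"))
    }
    est <- k / denom
    data.frame(parameter = parameter, strategy = strategy, estimate = est,
               se = sqrt(est * (1 - est) / denom), n = denom,
               horizon_months = horizon, note = note)
  }
  mean_row <- function(parameter, strategy, x, horizon = NA, note = "") {
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(data.frame(parameter = parameter, strategy = strategy,
                        estimate = NA_real_, se = NA_real_, n = 0,
                        horizon_months = horizon,
                        note = "no observations"))
    }
    data.frame(parameter = parameter, strategy = strategy,
               estimate = mean(x),
               se = stats::sd(x) / sqrt(length(x)), n = length(x),
               horizon_months = horizon, note = note)
  }
  na_row <- function(parameter, strategy, note) {
    data.frame(parameter = parameter, strategy = strategy,
               estimate = NA_real_, se = NA_real_, n = NA_integer_,
               horizon_months = NA_integer_, note = note)
  }

  alive <- !p$prosp_death
  heal_denom <- if (heal_denominator == "at_risk") sum(alive) else n
  rows <- list(
    binom_row("complication", "usual_care", sum(p$retro_hosp), n, 12),
    binom_row("complication", "specialist_clinic", sum(p$prosp_hosp), n, 3),
    binom_row("healing", "specialist_clinic", sum(p$prosp_healed),
              heal_denom, 3,
              note = paste("denominator =", heal_denominator)),
    binom_row("death_all_cause", "shared", sum(p$prosp_death), n, 3,
              note = "short-window estimate; annualise as 1-(1-p)^4"),
    na_row("healing", "usual_care", "literature input; not observed"),
    na_row("recurrence", "both", "not estimable from the windows"),
    na_row("death_wound", "both",
           "literature input (hazard-ratio derivation)"))

  u_unc <- mean_row("utility.uncomplicated", "shared", p$u_baseline)
  rows <- c(rows, list(
    u_unc,
    mean_row("utility.healed", "shared",
             p$u_month3[p$prosp_healed & alive]),
    {
      r <- u_unc
      r$parameter <- "utility.hospitalised"
      r$estimate <- r$estimate - 0.1
      r$note <- "uncomplicated estimate minus 0.1 decrement"
      r
    }))

  retro <- cohort$retrospective
  prosp <- cohort$prospective
  total_cost <- function(d, state) {
    idx <- d$state == state
    d$cost_out_of_pocket[idx] + d$cost_health_system[idx]
  }
  rows <- c(rows, list(
    mean_row("cost.uncomplicated", "usual_care",
             total_cost(retro, "uncomplicated")),
    mean_row("cost.hospitalised", "usual_care",
             total_cost(retro, "hospitalised")),
    na_row("cost.healed", "usual_care",
           "no healed months in the retrospective window"),
    mean_row("cost.uncomplicated", "specialist_clinic",
             total_cost(prosp, "uncomplicated")),
    mean_row("cost.hospitalised", "specialist_clinic",
             total_cost(prosp, "hospitalised")),
    mean_row("cost.healed", "specialist_clinic",
             total_cost(prosp, "healed"))))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("wound_param_estimates", "data.frame"))
}

#' @export
print.wound_param_estimates <- function(x, ...) {
  y <- as.data.frame(x)
  y$estimate <- signif(y$estimate, 4)
  y$se <- signif(y$se, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write / read a cohort as plain CSV files
#'
#' Writes `<prefix>_patients.csv`, `<prefix>_retrospective.csv` and
#' `<prefix>_prospective.csv` under `dir`; `read_cohort` reads them back.
#' The generating parameters are not serialised — a cohort read from disk
#' carries `generating_params = NULL`.
#'
#' @param cohort A `wound_cohort`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `write_cohort`: the paths written, invisibly. `read_cohort`:
#'   a `wound_cohort`.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "wound_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("patients", "retrospective",
                                   "prospective"), ".csv"))
  utils::write.csv(cohort$patients, paths[1], row.names = FALSE)
  utils::write.csv(cohort$retrospective, paths[2], row.names = FALSE)
  utils::write.csv(cohort$prospective, paths[3], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, prefix = "cohort") {
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("patients", "retrospective",
                                   "prospective"), ".csv"))
  if (!all(file.exists(paths))) {
    stop("cohort files not found under ", dir, call. = FALSE)
  }
  patients <- utils::read.csv(paths[1])
  # all-NA integer columns (e.g. event months in cohorts without events)
  # deserialise as logical; restore the documented column types
  for (col in c("retro_hosp_month", "prosp_heal_week", "prosp_hosp_month",
                "prosp_death_month")) {
    patients[[col]] <- as.integer(patients[[col]])
  }
  structure(list(patients = patients,
                 retrospective = utils::read.csv(paths[2]),
                 prospective = utils::read.csv(paths[3]),
                 generating_params = NULL, seed = NULL),
            class = "wound_cohort")
}
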