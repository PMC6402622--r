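#' Per-strategy model inputs
#'
#' Bundles and validates everything the Markov engine needs for one care
#' strategy: transition probabilities on their native horizons, per-state
#' monthly costs split by payer (patient out-of-pocket vs health system,
#' 2017 AUD), and per-state utility weights. Mortality inputs are stored
#' per strategy even though the model assumes them equal across strategies,
#' so both strategies are handled uniformly.
#'
#' The complicated-with-hospitalisation state carries the wound-related
#' mortality rate (derived via the hazard ratio of dying when hospitalised
#' with a wound); the uncomplicated and healed states carry background
#' all-cause mortality. By construction the hospitalised utility is the
#' uncomplicated utility minus a 0.1 decrement.
#'
#' @param label Strategy name, e.g. `"usual_care"`.
#' @param p_complication [horizon_prob]: wound deterioration requiring
#'   hospitalisation.
#' @param p_heal [horizon_prob]: complete healing of an uncomplicated wound.
#' @param p_death_all_cause [horizon_prob]: background all-cause mortality
#'   (annual in this study).
#' @param p_death_wound [horizon_prob]: wound-related mortality applied in
#'   the hospitalised state (annual).
#' @param p_recurrence [horizon_prob]: wound recurrence after healing
#'   (annual).
#' @param cost_out_of_pocket,cost_health_system Named numeric vectors of
#'   monthly costs (AUD) over the four states; `dead` must be 0.
#' @param utilities Named numeric vector of utility weights in \[0, 1\] per
#'   year of occupancy over the four states; `dead` must be 0.
#' @return An object of class `strategy_params`.
#' @export
#' @examples
#' sp <- strategy_params(
#'   label = "usual_care",
#'   p_complication = horizon_prob(0.379, 12),
#'   p_heal = horizon_prob(0.228, 3),
#'   p_death_all_cause = horizon_prob(0.016, 12),
#'   p_death_wound = horizon_prob(0.024, 12),
#'   p_recurrence = horizon_prob(0.557, 12),
#'   cost_out_of_pocket = c(uncomplicated = 215, hospitalised = 0,
#'                          healed = 34, dead = 0),
#'   cost_health_system = c(uncomplicated = 306, hospitalised = 30319,
#'                          healed = 34, dead = 0),
#'   utilities = c(uncomplicated = 0.69, hospitalised = 0.59,
#'                 healed = 0.89, dead = 0))
#' build_transition_matrix(sp)
strategy_params <- function(label,
                            p_complication, p_heal,
                            p_death_all_cause, p_death_wound, p_recurrence,
                            cost_out_of_pocket, cost_health_system,
                            utilities) {
  probs <- list(p_complication = p_complication, p_heal = p_heal,
                p_death_all_cause = p_death_all_cause,
                p_death_wound = p_death_wound, p_recurrence = p_recurrence)
  for (nm in names(probs)) {
    if (!inherits(probs[[nm]], "horizon_prob")) {
      stop("`", nm, "` must be a horizon_prob", call. = FALSE)
    }
  }
  oop <- state_vector(cost_out_of_pocket, "out-of-pocket cost")
  hs <- state_vector(cost_health_system, "health-system cost")
  u <- state_vector(utilities, "utility")
  if (any(oop < 0) || any(hs < 0)) {
    stop("costs must be non-negative", call. = FALSE)
  }
  if (any(u < 0) || any(u > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (oop[["dead"]] != 0 || hs[["dead"]] != 0 || u[["dead"]] != 0) {
    stop("the dead state must have zero cost and zero utility",
         call. = FALSE)
  }
  structure(c(list(label = as.character(label)), probs,
              list(cost_out_of_pocket = oop, cost_health_system = hs,
                   utilities = u)),
            class = "strategy_params")
}

#' @export
print.strategy_params <- function(x, ...) {
  cat("Strategy:", x$label, "\n")
  cat(sprintf("  complication %.3f/%dm, healing %.3f/%dm, recurrence %.3f/%dm\n",
              x$p_complication$value, x$p_complication$horizon_months,
              x$p_heal$value, x$p_heal$horizon_months,
              x$p_recurrence$value, x$p_recurrence$horizon_months))
  cat(sprintf("  mortality: all-cause %.3f, wound-related %.3f (annual)\n",
              x$p_death_all_cause$value, x$p_death_wound$value))
  cat("  monthly cost (oop + health system, AUD):\n")
  tot <- x$cost_out_of_pocket + x$cost_health_system
  for (s in wound_states()) {
    cat(sprintf("    %-13s %8.0f + %8.0f = %8.0f   utility %.2f\n", s,
                x$cost_out_of_pocket[[s]], x$cost_health_system[[s]],
                tot[[s]], x$utilities[[s]]))
  }
  invisible(x)
}

#' Assemble the monthly transition matrix for a strategy
#'
#' Converts every transition probability to the monthly cycle length and
#' assembles the 4x4 row-stochastic matrix with the model's structural
#' constraints: patients cannot move from the hospitalised state directly
#' to healed, cannot remain hospitalised for more than one cycle (one-cycle
#' tunnel, reflecting a median length of stay of about a month), healed
#' patients cannot be hospitalised without first recurring, and dead is
#' absorbing. The probability of remaining in a state is one minus the sum
#' of the exit probabilities.
#'
#' @param sp A [strategy_params] object.
#' @return A `transition_matrix`: 4x4 numeric matrix, rows = from-state,
#'   columns = to-state, each row summing to 1.
#' @export
build_transition_matrix <- function(sp) {
  stopifnot(inherits(sp, "strategy_params"))
  st <- wound_states()
  m_comp <- to_monthly_probability(sp$p_complication)
  m_heal <- to_monthly_probability(sp$p_heal)
  m_death_all <- to_monthly_probability(sp$p_death_all_cause)
  m_death_wound <- to_monthly_probability(sp$p_death_wound)
  m_rec <- to_monthly_probability(sp$p_recurrence)

  tm <- matrix(0, .n_states, .n_states, dimnames = list(from = st, to = st))
  exits <- list(
    uncomplicated = c(hospitalised = m_comp, healed = m_heal,
                      dead = m_death_all),
    hospitalised = c(dead = m_death_wound),
    healed = c(uncomplicated = m_rec, dead = m_death_all)
  )
  # the hospitalised tunnel empties into uncomplicated, not back into itself
  stay_state <- c(uncomplicated = "uncomplicated",
                  hospitalised = "uncomplicated", healed = "healed")
  for (from in names(exits)) {
    ex <- exits[[from]]
    if (sum(ex) > 1) {
      stop(sprintf(
        "monthly exit probabilities from state '%s' sum to %.4f > 1 (%s)",
        from, sum(ex),
        paste(sprintf("%s=%.4f", names(ex), ex), collapse = ", ")),
        call. = FALSE)
    }
    tm[from, names(ex)] <- ex
    tm[from, stay_state[[from]]] <- tm[from, stay_state[[from]]] + 1 - sum(ex)
  }
  tm["dead", "dead"] <- 1
  structure(tm, class = c("transition_matrix", "matrix", "array"))
}
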