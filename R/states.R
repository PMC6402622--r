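#' Health states of the wound-care Markov model
#'
#' The model tracks a cohort of chronic-wound patients through four health
#' states: living with an uncomplicated wound, hospitalised with a wound
#' complication, healed, and dead. Dead is the unique absorbing state.
#' The hospitalised state is a one-cycle tunnel: a patient cannot remain in
#' it for two consecutive monthly cycles, and cannot move from it directly
#' to healed.
#'
#' @return Character vector of the four state labels, in model order.
#' @export
#' @examples
#' wound_states()
wound_states <- function() {
  c("uncomplicated", "hospitalised", "healed", "dead")
}

# number of states; used for dimension checks throughout
.n_states <- 4L

#' @rdname wound_states
#' @export
absorbing_state <- function() "dead"

# internal: named numeric vector over the four states from a list/vector,
# erroring (with `what` in the message) if any state is missing
state_vector <- function(x, what = "value") {
  st <- wound_states()
  x <- unlist(x)
  missing <- setdiff(st, names(x))
  if (length(missing) > 0) {
    stop(sprintf("missing %s for state(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- as.numeric(x[st])
  names(out) <- st
  out
}
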