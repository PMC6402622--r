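#' Probability attached to an observation horizon
#'
#' Model inputs are estimated over different time horizons (annual rates
#' from registries and the literature, 3-month rates from the study's
#' follow-up window), while the model cycles monthly. A horizon probability
#' keeps the native value and its horizon together so the conversion to the
#' monthly scale is explicit and checked.
#'
#' @param value Probability on its native horizon, in \[0, 1\].
#' @param horizon_months Positive integer number of months the probability
#'   refers to (1, 3 or 12 in this model).
#' @return An object of class `horizon_prob`: a list with elements `value`
#'   and `horizon_months`.
#' @export
#' @examples
#' horizon_prob(0.379, 12)  # annual hospitalisation probability
horizon_prob <- function(value, horizon_months) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < 0 || value > 1) {
    stop("`value` must be a single probability in [0, 1], got: ",
         format(value), call. = FALSE)
  }
  if (!is.numeric(horizon_months) || length(horizon_months) != 1 ||
      is.na(horizon_months) || horizon_months < 1 ||
      horizon_months != round(horizon_months)) {
    stop("`horizon_months` must be a positive integer, got: ",
         format(horizon_months), call. = FALSE)
  }
  structure(list(value = as.numeric(value),
                 horizon_months = as.integer(horizon_months)),
            class = "horizon_prob")
}

#' @export
print.horizon_prob <- function(x, ...) {
  cat(sprintf("probability %.4g over %d month(s) (monthly %.4g)\n",
              x$value, x$horizon_months, to_monthly_probability(x)))
  invisible(x)
}

#' Convert a probability to the monthly cycle length
#'
#' Converts a probability observed over `t` months to the per-month
#' probability under a constant-rate assumption:
#' `p_month = 1 - (1 - p_t)^(1/t)`. Compounding the monthly probability
#' over `t` cycles recovers the native value exactly.
#'
#' @param p A [horizon_prob], or a plain probability when
#'   `horizon_months` is given.
#' @param horizon_months Horizon in months when `p` is a bare numeric.
#' @return Monthly probability in `[0, p]`.
#' @export
#' @examples
#' to_monthly_probability(horizon_prob(0.379, 12))
#' to_monthly_probability(0.228, 3)
to_monthly_probability <- function(p, horizon_months = NULL) {
  if (!inherits(p, "horizon_prob")) {
    if (is.null(horizon_months)) {
      stop("`horizon_months` is required when `p` is not a horizon_prob",
           call. = FALSE)
    }
    p <- horizon_prob(p, horizon_months)
  }
  1 - (1 - p$value)^(1 / p$horizon_months)
}
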