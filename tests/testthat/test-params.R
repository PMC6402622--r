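usual_sp <- function() {
  strategy_params_from_config(default_config(), "usual_care")
}

test_that("strategy parameters enforce the model's value constraints", {
  sp <- usual_sp()
  expect_s3_class(sp, "strategy_params")
  # the packaged defaults encode the 0.1 hospitalisation decrement
  expect_equal(sp$utilities[["hospitalised"]],
               sp$utilities[["uncomplicated"]] - 0.1)

  bad_cost <- c(uncomplicated = -5, hospitalised = 0, healed = 0, dead = 0)
  expect_error(
    strategy_params("x", sp$p_complication, sp$p_heal,
                    sp$p_death_all_cause, sp$p_death_wound,
                    sp$p_recurrence, bad_cost, sp$cost_health_system,
                    sp$utilities),
    "non-negative")
  bad_dead_u <- sp$utilities
  bad_dead_u[["dead"]] <- 0.5
  expect_error(
    strategy_params("x", sp$p_complication, sp$p_heal,
                    sp$p_death_all_cause, sp$p_death_wound,
                    sp$p_recurrence, sp$cost_out_of_pocket,
                    sp$cost_health_system, bad_dead_u),
    "zero cost and zero utility")
})

test_that("all-zero probabilities give the identity up to structural zeros", {
  z <- horizon_prob(0, 12)
  sp <- strategy_params("null", z, z, z, z, z,
                        cost_out_of_pocket = c(uncomplicated = 0,
                                               hospitalised = 0,
                                               healed = 0, dead = 0),
                        cost_health_system = c(uncomplicated = 0,
                                               hospitalised = 0,
                                               healed = 0, dead = 0),
                        utilities = c(uncomplicated = 0.5,
                                      hospitalised = 0.5,
                                      healed = 0.5, dead = 0))
  tm <- build_transition_matrix(sp)
  expect_equal(tm["uncomplicated", ], c(uncomplicated = 1, hospitalised = 0,
                                        healed = 0, dead = 0))
  # the tunnel cannot hold: its residual goes back to uncomplicated
  expect_equal(tm["hospitalised", ], c(uncomplicated = 1, hospitalised = 0,
                                       healed = 0, dead = 0))
  expect_equal(tm["healed", ], c(uncomplicated = 0, hospitalised = 0,
                                 healed = 1, dead = 0))
  expect_equal(tm["dead", ], c(uncomplicated = 0, hospitalised = 0,
                               healed = 0, dead = 1))
})

test_that("the usual-care matrix matches the converted monthly inputs", {
  tm <- build_transition_matrix(usual_sp())
  row <- tm["uncomplicated", ]
  expect_equal(row[["hospitalised"]], to_monthly_probability(0.379, 12))
  expect_equal(row[["healed"]], to_monthly_probability(0.228, 3))
  expect_equal(row[["dead"]], to_monthly_probability(0.016, 12))
  expect_equal(row[["hospitalised"]], 0.0389, tolerance = 1e-2)
  expect_equal(row[["healed"]], 0.0826, tolerance = 1e-2)
  expect_equal(row[["dead"]], 0.0013, tolerance = 5e-2)
  expect_equal(row[["uncomplicated"]], 1 - sum(row[-1]))
  expect_equal(tm["hospitalised", "dead"], to_monthly_probability(0.024, 12))
  expect_equal(tm["healed", "uncomplicated"],
               to_monthly_probability(0.557, 12))
})

test_that("every valid matrix is row-stochastic with the structural zeros", {
  set.seed(41)
  for (i in 1:20) {
    tm <- build_transition_matrix(random_strategy_params())
    expect_equal(unname(rowSums(tm)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(tm >= 0))
    expect_identical(tm["hospitalised", "healed"], 0)
    expect_identical(tm["hospitalised", "hospitalised"], 0)
    expect_identical(tm["healed", "hospitalised"], 0)
    expect_equal(unname(tm["dead", ]), c(0, 0, 0, 1))
  }
})

test_that("incompatible monthly exit probabilities fail naming the row", {
  sp <- usual_sp()
  sp$p_complication <- horizon_prob(0.95, 1)
  sp$p_heal <- horizon_prob(0.9, 1)
  expect_error(build_transition_matrix(sp), "uncomplicated.*sum")
})
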