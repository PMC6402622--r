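test_that("trace propagation handles identity and absorbing extremes", {
  ident <- diag(4)
  init <- c(0.4, 0.1, 0.3, 0.2)
  tr <- run_cohort(ident, 12, init)
  for (k in 1:13) expect_equal(unname(tr[k, ]), init)

  absorbing <- matrix(0, 4, 4)
  absorbing[, 4] <- 1
  tr <- run_cohort(absorbing, 5, c(1, 0, 0, 0))
  for (k in 2:6) expect_equal(unname(tr[k, ]), c(0, 0, 0, 1))
})

test_that("the trace satisfies its occupancy invariants", {
  set.seed(99)
  for (i in 1:10) {
    tm <- build_transition_matrix(random_strategy_params())
    tr <- run_cohort(tm, 12)
    expect_equal(unname(rowSums(tr)), rep(1, 13), tolerance = 1e-12)
    expect_equal(unname(tr[1, ]), c(1, 0, 0, 0))
    expect_true(all(diff(tr[, "dead"]) >= -1e-15))
  }
})

test_that("the 12-cycle trace equals the matrix-power oracle", {
  set.seed(7)
  tm <- build_transition_matrix(
    strategy_params_from_config(default_config(), "usual_care"))
  tr <- run_cohort(tm, 12)
  # independent oracle: explicit matrix powers
  pow <- diag(4)
  for (k in 1:12) {
    pow <- pow %*% tm
    expect_equal(unname(tr[k + 1, ]),
                 unname(as.numeric(c(1, 0, 0, 0) %*% pow)),
                 tolerance = 1e-14)
  }
})

test_that("dimension and normalisation errors are caught", {
  tm <- diag(4)
  expect_error(run_cohort(diag(3)), "4x4")
  expect_error(run_cohort(tm, init = c(1, 0, 0)), "length")
  expect_error(run_cohort(tm, init = c(0.5, 0, 0, 0)), "sum to 1")
})

test_that("accrual reproduces hand-computable traces", {
  sp <- strategy_params_from_config(default_config(), "usual_care")
  # cohort parked in healed for all 12 accrual cycles: QALYs = utility
  parked <- matrix(rep(c(0, 0, 1, 0), 13), 13, 4, byrow = TRUE,
                   dimnames = list(paste0("cycle_", 0:12), wound_states()))
  out <- accrue_outcomes(parked, sp, convention = "end_of_cycle")
  expect_equal(out$total_qalys, 0.89)

  # zero-cost map zeroes the cost regardless of the trace
  sp0 <- sp
  sp0$cost_out_of_pocket[] <- 0
  sp0$cost_health_system[] <- 0
  tr <- run_cohort(build_transition_matrix(sp), 12)
  out0 <- accrue_outcomes(tr, sp0)
  expect_identical(out0$total_cost, 0)
  expect_error(accrue_outcomes(tr, sp, perspective = "societal"),
               "arg")
})

test_that("with equal utilities and no mortality, QALYs equal the utility", {
  u <- 0.73
  z <- horizon_prob(0, 12)
  sp <- strategy_params("no-death", horizon_prob(0.3, 12),
                        horizon_prob(0.2, 3), z, z,
                        horizon_prob(0.5, 12),
                        cost_out_of_pocket = c(uncomplicated = 1,
                                               hospitalised = 2,
                                               healed = 3, dead = 0),
                        cost_health_system = c(uncomplicated = 0,
                                               hospitalised = 0,
                                               healed = 0, dead = 0),
                        utilities = c(uncomplicated = u, hospitalised = u,
                                      healed = u, dead = 0))
  tr <- run_cohort(build_transition_matrix(sp), 12)
  out <- accrue_outcomes(tr, sp, convention = "end_of_cycle")
  expect_equal(out$total_qalys, u, tolerance = 1e-12)
})

test_that("accrual is additive over a split horizon", {
  sp <- strategy_params_from_config(default_config(), "specialist_clinic")
  tm <- build_transition_matrix(sp)
  full <- accrue_outcomes(run_cohort(tm, 12), sp,
                          convention = "end_of_cycle")
  first <- run_cohort(tm, 6)
  head6 <- accrue_outcomes(first, sp, convention = "end_of_cycle")
  cont <- run_cohort(tm, 6, init = first[7, ])
  tail6 <- accrue_outcomes(cont, sp, convention = "end_of_cycle")
  expect_equal(full$total_cost, head6$total_cost + tail6$total_cost,
               tolerance = 1e-9)
  expect_equal(full$total_qalys, head6$total_qalys + tail6$total_qalys,
               tolerance = 1e-12)
})

test_that("payer perspectives decompose the total cost", {
  cfg <- default_config()
  for (conv in c("all_cycles", "end_of_cycle", "start_of_cycle",
                 "half_cycle")) {
    for (snm in c("usual_care", "specialist_clinic")) {
      sp <- strategy_params_from_config(cfg, snm)
      tr <- run_cohort(build_transition_matrix(sp), 12)
      total <- accrue_outcomes(tr, sp, "total", conv)
      hs <- accrue_outcomes(tr, sp, "health_system", conv)
      oop <- accrue_outcomes(tr, sp, "out_of_pocket", conv)
      expect_equal(total$total_cost, total$oop_cost +
                     total$health_system_cost, tolerance = 1e-9)
      expect_equal(total$total_cost, hs$total_cost + oop$total_cost,
                   tolerance = 1e-9)
      expect_identical(hs$oop_cost, 0)
      expect_identical(oop$health_system_cost, 0)
    }
  }
})

test_that("hospitalisation behaves as a one-cycle tunnel", {
  set.seed(11)
  for (i in 1:5) {
    sp <- random_strategy_params()
    tm <- build_transition_matrix(sp)
    tr <- run_cohort(tm, 12)
    m_comp <- to_monthly_probability(sp$p_complication)
    # occupancy of the tunnel depends only on the uncomplicated inflow
    for (k in 1:12) {
      expect_equal(tr[k + 1, "hospitalised"],
                   tr[k, "uncomplicated"] * m_comp, tolerance = 1e-12)
    }
  }
})

test_that("the tidy accrual table reconciles with the totals", {
  cfg <- default_config()
  sp <- strategy_params_from_config(cfg, "usual_care")
  out <- run_deterministic(cfg)$usual
  tab <- trace_accrual_table(out, sp)
  expect_named(tab, c("cycle", "state", "occupancy", "cost", "qaly"))
  expect_equal(sum(tab$cost), out$total_cost, tolerance = 1e-9)
  expect_equal(sum(tab$qaly), out$total_qalys, tolerance = 1e-12)
})
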