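test_that("beta fits conserve the mean and the pseudo-sample size", {
  expect_equal(fit_beta(0.5, 2), c(shape1 = 1, shape2 = 1))
  expect_equal(fit_beta(0.345, 26), c(shape1 = 8.97, shape2 = 17.03))
  sh <- fit_beta(0.016, 100)
  expect_equal(unname(sum(sh)), 100)
  # analytic mean identity over a parameter sweep
  for (m in c(0.034, 0.228, 0.59, 0.89)) {
    sh <- fit_beta(m, 37)
    expect_equal(unname(sh[1] / sum(sh)), m, tolerance = 1e-9)
  }
  expect_error(fit_beta(0, 10), "degenerate")
  expect_error(fit_beta(1, 10), "degenerate")
  expect_error(fit_beta(0.5, 0), "positive")
})

test_that("gamma fits reproduce the stated mean and cv", {
  expect_equal(fit_gamma(1000, 1), c(shape = 1, scale = 1000))
  expect_equal(fit_gamma(30319, 0.2), c(shape = 25, scale = 1212.76))
  for (m in c(68, 521, 30319)) {
    sh <- fit_gamma(m, 0.2)
    expect_equal(unname(sh[1] * sh[2]), m, tolerance = 1e-9)
    expect_equal(unname(sqrt(sh[1]) * sh[2]), m * 0.2, tolerance = 1e-9)
  }
  expect_error(fit_gamma(0, 0.2), "positive")
  expect_error(fit_gamma(100, 0), "positive")
})

test_that("sampled means agree with the fitted distributions", {
  set.seed(205)
  n <- 1e6
  sh <- fit_beta(0.345, 26)
  x <- rbeta(n, sh[1], sh[2])
  se <- sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - 0.345), 3 * se)

  sg <- fit_gamma(30319, 0.2)
  y <- rgamma(n, shape = sg[1], scale = sg[2])
  expect_lt(abs(mean(y) - 30319), 3 * sd(y) / sqrt(n))
})

test_that("a zero-dispersion PSA equals the deterministic result", {
  cfg <- zero_dispersion(test_config())
  det <- run_deterministic(cfg)
  psa <- run_psa(cfg, n_sims = 1, seed = 3)
  expect_equal(psa$delta_cost, det$delta_cost, tolerance = 1e-9)
  expect_equal(psa$delta_qalys, det$delta_qalys, tolerance = 1e-12)
})

test_that("the same seed reproduces the PSA bit for bit", {
  cfg <- test_config(n_psa = 150)
  a <- run_psa(cfg, seed = 17)
  b <- run_psa(cfg, seed = 17)
  expect_identical(a$delta_cost, b$delta_cost)
  expect_identical(a$delta_qalys, b$delta_qalys)
  c <- run_psa(cfg, seed = 18)
  expect_false(identical(a$delta_cost, c$delta_cost))
})

test_that("PSA draws are paired and sized as requested", {
  psa <- run_psa(test_config(), n_sims = 137, seed = 5)
  expect_identical(psa$n_sims, 137L)
  expect_length(psa$delta_cost, 137)
  expect_length(psa$delta_qalys, 137)
  expect_identical(psa$delta_cost,
                   psa$specialist_cost - psa$usual_cost)
  d <- psa_draws(psa)
  expect_identical(names(d), c("sim_id", "delta_cost", "delta_qalys"))
  expect_identical(nrow(d), 137L)
})

test_that("excessive infeasible draws abort with a diagnostic", {
  cfg <- test_config()
  # near-degenerate bimodal betas throw most draws outside feasibility
  cfg$uncertainty$probability_effective_n <- list(default = 0.05)
  expect_error(run_psa(cfg, n_sims = 400, seed = 1),
               "redraws|feasible")
})

test_that("shared parameters use one draw per simulation", {
  cfg <- test_config()
  # make every strategy-specific parameter fixed; leave mortality random
  cfg$uncertainty$cost_cv <- 0
  cfg$uncertainty$utility_effective_n <- Inf
  pen <- list(default = Inf,
              usual_care.death_all_cause = 50,
              usual_care.death_wound = 50)
  cfg$uncertainty$probability_effective_n <- pen
  psa <- run_psa(cfg, n_sims = 50, seed = 9)
  # mortality affects both arms identically through shared draws, so the
  # QALY increment varies far less than either arm's absolute QALYs
  expect_gt(sd(psa$usual_qalys), 10 * sd(psa$delta_qalys))
})
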