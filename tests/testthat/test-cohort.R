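test_that("cohort generation validates n and reproduces under a seed", {
  expect_error(generate_cohort(0), "positive integer")
  expect_error(generate_cohort(-3), "positive integer")
  expect_error(generate_cohort(2.5), "positive integer")
  a <- generate_cohort(29, seed = 7)
  b <- generate_cohort(29, seed = 7)
  expect_identical(a$patients, b$patients)
  expect_identical(a$retrospective, b$retrospective)
  expect_identical(a$prospective, b$prospective)
  expect_false(identical(a$patients, generate_cohort(29, seed = 8)$patients))
})

test_that("patient records respect their structural invariants", {
  coh <- generate_cohort(400, seed = 31)
  p <- coh$patients
  expect_true(all(p$u_baseline >= 0 & p$u_baseline <= 1))
  expect_true(all(is.na(p$u_month3) | (p$u_month3 >= 0 & p$u_month3 <= 1)))
  expect_true(all(is.na(p$retro_hosp_month) |
                    p$retro_hosp_month %in% 1:12))
  expect_true(all(is.na(p$prosp_heal_week) | p$prosp_heal_week %in% 1:13))
  expect_true(all(is.na(p$prosp_hosp_month) | p$prosp_hosp_month %in% 1:3))
  expect_true(all(p$age >= 25 & p$age <= 92))
  # healed patients' 3-month utilities come from the healed distribution
  expect_gt(mean(p$u_month3[p$prosp_healed]),
            mean(p$u_month3[!p$prosp_healed & !p$prosp_death]))
  # patient-months stay within their windows and carry costs
  expect_true(all(coh$retrospective$month %in% 1:12))
  expect_true(all(coh$prospective$month %in% 1:3))
  expect_identical(nrow(coh$retrospective), 400L * 12L)
  expect_identical(nrow(coh$prospective), 400L * 3L)
  dead_months <- coh$prospective$state == "dead"
  expect_true(all(coh$prospective$cost_out_of_pocket[dead_months] == 0))
})

test_that("cohort composition matches the targets in expectation", {
  coh <- generate_cohort(4000, seed = 12)
  p <- coh$patients
  se_prop <- function(pr, n) sqrt(pr * (1 - pr) / n)
  expect_lt(abs(mean(p$wound_type == "venous_leg") - 0.73),
            3 * se_prop(0.73, 4000))
  expect_lt(abs(mean(p$sex == "male") - 0.5), 3 * se_prop(0.5, 4000))
  expect_lt(abs(mean(p$age) - 72), 1)
  expect_lt(abs(mean(p$retro_hosp) - 0.379), 3 * se_prop(0.379, 4000))
  expect_lt(abs(mean(p$prosp_healed) - 0.345),
            3 * se_prop(0.345, 4000) + 0.005)  # small mortality censoring
})

test_that("the healing estimator reproduces a 9-of-20 cohort", {
  coh <- hand_cohort(n = 20, healed = 9)
  est <- estimate_params(coh)
  heal <- est[est$parameter == "healing" &
                est$strategy == "specialist_clinic", ]
  expect_equal(heal$estimate, 0.45)
  expect_identical(heal$n, 20)
  # the ambiguous denominator is a parameter: with one death, at-risk
  # and all-enrolled denominators differ
  coh2 <- hand_cohort(n = 21, healed = 9, deaths = 1)
  at_risk <- estimate_params(coh2, heal_denominator = "at_risk")
  all_enr <- estimate_params(coh2, heal_denominator = "all")
  expect_equal(at_risk[at_risk$parameter == "healing" &
                         at_risk$strategy == "specialist_clinic",
                       "estimate"], 9 / 20)
  expect_equal(all_enr[all_enr$parameter == "healing" &
                         all_enr$strategy == "specialist_clinic",
                       "estimate"], 9 / 21)
})

test_that("identical utilities collapse both utility estimates", {
  coh <- hand_cohort(n = 10, healed = 4, u_baseline = 0.8, u_month3 = 0.8)
  est <- estimate_params(coh)
  u <- est[grepl("^utility", est$parameter), ]
  expect_equal(u[u$parameter == "utility.uncomplicated", "estimate"], 0.8)
  expect_equal(u[u$parameter == "utility.healed", "estimate"], 0.8)
  expect_equal(u[u$parameter == "utility.hospitalised", "estimate"], 0.7)
})

test_that("degenerate cohorts yield missing estimates, not crashes", {
  coh <- hand_cohort(n = 3, healed = 0, deaths = 3)
  est <- estimate_params(coh)
  heal <- est[est$parameter == "healing" &
                est$strategy == "specialist_clinic", ]
  expect_true(is.na(heal$estimate))
  expect_match(heal$note, "zero at-risk")
  empty <- list(patients = data.frame())
  expect_error(estimate_params(empty), "empty")
})

test_that("unobservable inputs are reported as missing with notes", {
  est <- estimate_params(generate_cohort(50, seed = 2))
  rec <- est[est$parameter == "recurrence", ]
  expect_true(is.na(rec$estimate))
  expect_match(rec$note, "not estimable")
  uh <- est[est$parameter == "healing" & est$strategy == "usual_care", ]
  expect_true(is.na(uh$estimate))
})

test_that("cohorts round-trip through CSV", {
  coh <- generate_cohort(25, seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$patients, coh$patients)
  expect_equal(back$retrospective, coh$retrospective)
  expect_equal(back$prospective, coh$prospective)
  est1 <- estimate_params(coh)
  est2 <- estimate_params(back)
  expect_equal(est1$estimate, est2$estimate)
  expect_error(read_cohort(file.path(dir, "missing")), "not found")
})

test_that("estimates plugged back into the pipeline reproduce the truth", {
  # large-n cohort, estimates replace the config's study-derived inputs;
  # the deterministic results must approach those from the true values
  cfg <- default_config()
  est <- estimate_params(generate_cohort(20000, seed = 14))
  pick <- function(par, strat) {
    est[est$parameter == par & est$strategy == strat, "estimate"]
  }
  cfg2 <- cfg
  cfg2$strategies$usual_care$probabilities$complication$value <-
    pick("complication", "usual_care")
  cfg2$strategies$specialist_clinic$probabilities$complication$value <-
    pick("complication", "specialist_clinic")
  cfg2$strategies$specialist_clinic$probabilities$healing$value <-
    pick("healing", "specialist_clinic")
  u_unc <- pick("utility.uncomplicated", "shared")
  cfg2$utilities$uncomplicated <- u_unc
  cfg2$utilities$hospitalised <- u_unc - 0.1
  cfg2$utilities$healed <- pick("utility.healed", "shared")
  truth <- run_deterministic(cfg)
  fitted <- run_deterministic(cfg2)
  expect_lt(abs(fitted$delta_qalys - truth$delta_qalys), 0.01)
  expect_lt(abs(fitted$delta_cost - truth$delta_cost) /
              abs(truth$delta_cost), 0.05)
})
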