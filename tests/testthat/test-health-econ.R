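test_that("parameter definitions enforce ranges and supports", {
  expect_error(param("p", "probability", 0.5, 0.6, 0.9), "low <= base <= high")
  expect_error(param("p", "probability", 1.2, 0, 1.5), "outside support")
  expect_error(param("c", "cost", -5), "outside support")
  expect_error(parameter_set(param("a", "cost", 1), param("a", "cost", 2)),
               "duplicate")
  ps <- parameter_set(param("a", "cost", 1), param("b", "utility", 0.5))
  expect_equal(base_values(ps), c(a = 1, b = 0.5))
  expect_error(apply_overrides(base_values(ps), list(zzz = 1)), "zzz")
  expect_equal(apply_overrides(base_values(ps), list(a = 9))[["a"]], 9)
})

full_health_model <- function(utility = 1, cost = 0) {
  state_model(
    list(health_state("alive", cost_per_cycle = cost, utility = utility),
         health_state("dead", absorbing = TRUE)),
    diag(2), cycle_length = 1
  )
}

test_that("outcome accumulation matches hand summation", {
  entry <- c(alive = 1, dead = 0)

  # full-health survivor, 10 undiscounted years
  sm <- full_health_model()
  plan <- cycle_plan(10, 1, 0, 0, half_cycle_correction = FALSE)
  res <- accumulate_outcomes(run_cohort(sm, entry, plan), sm, plan)
  expect_equal(res$life_years, 10)
  expect_equal(res$qalys, 10)
  expect_equal(res$total_cost, 0)
  # no deaths: half-cycle correction changes nothing
  plan_hc <- cycle_plan(10, 1, 0, 0, half_cycle_correction = TRUE)
  res_hc <- accumulate_outcomes(run_cohort(sm, entry, plan_hc), sm, plan_hc)
  expect_equal(res_hc$life_years, 10)

  # utility 0.5, cost 100/cycle, 3 annual cycles, upfront added on top
  sm2 <- full_health_model(utility = 0.5, cost = 100)
  plan3 <- cycle_plan(3, 1, 0, 0, half_cycle_correction = FALSE)
  res2 <- accumulate_outcomes(run_cohort(sm2, entry, plan3), sm2, plan3,
                              upfront_cost = 50)
  expect_equal(res2$qalys, 1.5)
  expect_equal(res2$total_cost, 350)

  # state-count mismatch is caught
  tr <- run_cohort(sm2, entry, plan3)
  sm3 <- random_valid_model(3, seed = 1)
  expect_error(accumulate_outcomes(tr, sm3, plan3), "do not match")
})

test_that("accumulation agrees with a cycle-by-cycle oracle on random models", {
  for (seed in 1:5) {
    sm <- random_valid_model(4, seed = seed)
    entry <- stats::setNames(c(0.6, 0.3, 0.1, 0), sm$state_names)
    plan <- cycle_plan(30, 1, 0.03, 0.015, half_cycle_correction = FALSE)
    tr <- run_cohort(sm, entry, plan)
    got <- accumulate_outcomes(tr, sm, plan, upfront_cost = 123)
    want <- naive_outcomes(unclass(tr), sm$cost_per_cycle, sm$utility,
                           !sm$absorbing, 1, 0.03, 0.015, upfront = 123)
    expect_equal(got$total_cost, want$total_cost, tolerance = 1e-10)
    expect_equal(got$life_years, want$life_years, tolerance = 1e-10)
    expect_equal(got$qalys, want$qalys, tolerance = 1e-10)
  }
})

test_that("half-cycle correction averages start and end occupancy at mid-cycle discounting", {
  alive <- health_state("alive", cost_per_cycle = 1000, utility = 0.8)
  dead <- health_state("dead", absorbing = TRUE)
  sm <- state_model(list(alive, dead),
                    matrix(c(0.5, 0.5, 0, 1), 2, 2, byrow = TRUE),
                    cycle_length = 1)
  plan <- cycle_plan(2, 1, 0.03, 0.03, half_cycle_correction = TRUE)
  res <- accumulate_outcomes(run_cohort(sm, c(alive = 1, dead = 0), plan), sm, plan)
  # occupancy alive: 1, 0.5, 0.25 -> trapezoid 0.75, 0.375 at t = 0.5, 1.5
  exp_cost <- 1000 * (0.75 * 1.03^-0.5 + 0.375 * 1.03^-1.5)
  exp_ly <- 0.75 * 1.03^-0.5 + 0.375 * 1.03^-1.5
  expect_equal(res$total_cost, exp_cost, tolerance = 1e-12)
  expect_equal(res$life_years, exp_ly, tolerance = 1e-12)
  expect_equal(res$qalys, 0.8 * exp_ly, tolerance = 1e-12)
})

test_that("costs are affine in unit costs and monotone in the discount rate", {
  entry <- c(alive = 1, dead = 0)
  make <- function(cost) {
    state_model(
      list(health_state("alive", cost_per_cycle = cost, utility = 0.7),
           health_state("dead", absorbing = TRUE)),
      matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE), cycle_length = 1
    )
  }
  plan <- cycle_plan(20, 1, 0.03, 0.03)
  r1 <- accumulate_outcomes(run_cohort(make(100), entry, plan), make(100), plan,
                            upfront_cost = 77)
  r2 <- accumulate_outcomes(run_cohort(make(200), entry, plan), make(200), plan,
                            upfront_cost = 77)
  expect_equal(r2$total_cost - 77, 2 * (r1$total_cost - 77), tolerance = 1e-12)

  rates <- c(0, 0.015, 0.03, 0.06)
  totals <- vapply(rates, function(r) {
    p <- cycle_plan(20, 1, r, r)
    accumulate_outcomes(run_cohort(make(100), entry, p), make(100), p)$total_cost
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("arm comparison is an exact antisymmetric subtraction with consistent labels", {
  a <- arm_result(103947, 11.18, 8.57)
  b <- arm_result(193932, 11.51, 8.69)
  cr <- compare_arms(a, b)
  expect_identical(cr$delta_cost, 193932 - 103947)
  expect_equal(cr$icer_per_qaly, cr$delta_cost / cr$delta_qaly)
  expect_identical(cr$dominance_label, "trade-off")

  rev <- compare_arms(b, a)
  expect_identical(rev$delta_cost, -cr$delta_cost)
  expect_identical(rev$delta_ly, -cr$delta_ly)
  expect_identical(rev$delta_qaly, -cr$delta_qaly)

  same <- compare_arms(a, a)
  expect_identical(same$delta_cost, 0)
  expect_true(is.na(same$icer_per_qaly))
  expect_true(is.na(same$icer_per_ly))
  expect_identical(same$dominance_label, "trade-off")

  expect_identical(compare_arms(b, arm_result(100, 11.18, 8.80))$dominance_label,
                   "dominant")
  expect_identical(compare_arms(a, arm_result(200000, 11, 8))$dominance_label,
                   "dominated")
})

test_that("net monetary benefit and headroom follow their defining formulas", {
  expect_identical(net_monetary_benefit(0, 0, 50000), 0)
  expect_identical(net_monetary_benefit(250, 0.1, 0), -250)
  expect_equal(net_monetary_benefit(89985, 0.13, 100000), 13000 - 89985)

  expect_identical(headroom(500, 0, 2)$headroom, 500)
  expect_identical(headroom(0, 20000, 0)$headroom, 0)
  expect_equal(headroom(886, 20000, 0.06)$headroom, 2086)
})

test_that("mixing pathway results reproduces the weighted mean and is exact when pathways coincide", {
  x <- arm_result(100, 5, 4)
  y <- arm_result(300, 7, 6)
  m <- mix_arms(list(x, y), c(0.25, 0.75))
  expect_equal(m$total_cost, 0.25 * 100 + 0.75 * 300, tolerance = 1e-12)
  expect_equal(m$qalys, 0.25 * 4 + 0.75 * 6, tolerance = 1e-12)
  z <- arm_result(123.456, 7.89, 6.54)
  same <- mix_arms(list(z, z), c(0.3, 0.7))
  expect_identical(same$total_cost, z$total_cost)
  expect_identical(same$qalys, z$qalys)
})
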