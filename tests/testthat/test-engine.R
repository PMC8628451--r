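test_that("state and model validation enforce the cohort-model invariants", {
  expect_error(health_state("s", utility = 1.2), "\\[0, 1\\]")
  expect_error(health_state("s", cost_per_cycle = -1), ">= 0")

  alive <- health_state("alive", utility = 1)
  dead <- health_state("dead", absorbing = TRUE)
  bad_rows <- matrix(c(0.6, 0.3, 0, 1), 2, 2, byrow = TRUE)
  expect_error(state_model(list(alive, dead), bad_rows), "do not sum to 1")

  # no absorbing state at all
  expect_error(
    state_model(list(alive, health_state("b", utility = 1)),
                diag(2)),
    "absorbing"
  )

  # absorbing state must keep its occupancy
  leaky <- matrix(c(0.5, 0.5, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_error(state_model(list(alive, dead), leaky), "identity transition row")

  # sub-tolerance drift is renormalised, not rejected
  drift <- matrix(c(0.5 + 1e-12, 0.5, 0, 1), 2, 2, byrow = TRUE)
  sm <- state_model(list(alive, dead), drift)
  expect_equal(rowSums(sm$transitions[[1]]), c(alive = 1, dead = 1))
})

test_that("run_cohort reproduces hand-computed occupancy", {
  alive <- health_state("alive", utility = 1)
  dead <- health_state("dead", absorbing = TRUE)

  # identity transitions: occupancy frozen at entry
  sm_id <- state_model(list(alive, dead), diag(2), cycle_length = 1)
  tr <- run_cohort(sm_id, c(alive = 0.7, dead = 0.3), cycle_plan(5, 1))
  expect_equal(dim(tr), c(6, 2))
  for (t in 1:6) expect_equal(unname(tr[t, ]), c(0.7, 0.3))

  # p(alive -> dead) = 0.5 per cycle: after two cycles 0.25 / 0.75
  sm <- state_model(list(alive, dead),
                    matrix(c(0.5, 0.5, 0, 1), 2, 2, byrow = TRUE),
                    cycle_length = 1)
  tr2 <- run_cohort(sm, c(alive = 1, dead = 0), cycle_plan(2, 1))
  expect_equal(unname(tr2[3, ]), c(0.25, 0.75))

  # horizon must be a multiple of the cycle length
  expect_error(cycle_plan(2.5, 1), "integer multiple")
  expect_error(run_cohort(sm, c(alive = 0.5, dead = 0.1), cycle_plan(2, 1)),
               "sum to 1")
})

test_that("run_cohort agrees with a naive multiplication oracle, including time-dependent models", {
  for (seed in 1:10) {
    n <- sample(3:5, 1)
    sm <- random_valid_model(n, seed = seed, time_dependent = seed %% 2 == 0)
    entry <- c(1, rep(0, n - 1))
    names(entry) <- sm$state_names
    tr <- run_cohort(sm, entry, cycle_plan(50, 1))
    oracle <- naive_trace(sm$transitions, unname(entry), 50)
    expect_lt(max(abs(unclass(tr) - oracle)), 1e-12)
  }
})

test_that("traces conserve probability and absorb monotonically", {
  for (seed in 11:25) {
    n <- sample(3:5, 1)
    sm <- random_valid_model(n, seed = seed)
    entry <- stats::setNames(c(1, rep(0, n - 1)), sm$state_names)
    tr <- run_cohort(sm, entry, cycle_plan(200, 1))
    expect_true(all(abs(rowSums(tr) - 1) < 1e-9))
    expect_true(all(tr >= -1e-15 & tr <= 1 + 1e-15))
    dead <- tr[, "dead"]
    expect_true(all(diff(dead) >= -1e-12))
  }
  # with positive per-cycle death risk everywhere, everyone eventually dies
  sm <- random_valid_model(4, seed = 99)
  m <- sm$transitions[[1]]
  m[1:3, 4] <- pmax(m[1:3, 4], 0.05)
  m[1:3, ] <- m[1:3, ] / rowSums(m[1:3, , drop = FALSE])
  sm2 <- state_model(sm$states, m, cycle_length = 1)
  tr <- run_cohort(sm2, stats::setNames(c(1, 0, 0, 0), sm2$state_names),
                   cycle_plan(500, 1))
  expect_gt(tr[nrow(tr), "dead"], 0.9999)
})

test_that("hazard-ratio adjustment follows the rate-scale transform", {
  expect_identical(hr_adjust_probability(0.2, 1), 0.2)
  expect_identical(hr_adjust_probability(0, 5), 0)
  # frozen arbitrary-precision value of 1 - 0.8^0.11
  expect_equal(hr_adjust_probability(0.2, 0.11), 0.0242469924637289446,
               tolerance = 1e-15)
  expect_error(hr_adjust_probability(1, 0.5), "undefined")
  expect_error(hr_adjust_probability(0.2, 0), "> 0")

  # monotone in both arguments; hr = 1 an exact fixed point
  ps <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(hr_adjust_probability(ps, 0.7)) > 0))
  hrs <- c(0.1, 0.5, 1, 2, 5)
  for (p in c(0.1, 0.5)) {
    vals <- vapply(hrs, function(h) hr_adjust_probability(p, h), numeric(1))
    expect_true(all(diff(vals) > 0))
    expect_identical(hr_adjust_probability(p, 1), p)
  }
})

test_that("discount factors follow 1/(1+r)^t", {
  expect_identical(discount_factor(0, 0.03), 1)
  expect_identical(discount_factor(10, 0), 1)
  expect_equal(discount_factor(2, 0.03), 0.942595909133754360, tolerance = 1e-15)
  expect_error(discount_factor(-1, 0.03))
})

test_that("tree rollback matches hand enumeration and brute force", {
  # identity: a single certain branch passes the terminal through
  single <- decision_node("root", list(
    tree_branch(1, cost = 0, child = c(A = 0.3, B = 0.7))
  ))
  rb <- rollback_tree(single)
  expect_equal(rb$entry, c(A = 0.3, B = 0.7))
  expect_identical(rb$upfront_cost, 0)

  # two-branch hand enumeration
  two <- decision_node("root", list(
    tree_branch(0.5, cost = 100, child = c(A = 1, B = 0)),
    tree_branch(0.5, cost = 300, child = c(A = 0, B = 1))
  ))
  rb2 <- rollback_tree(two)
  expect_equal(rb2$entry, c(A = 0.5, B = 0.5))
  expect_equal(rb2$upfront_cost, 200)

  # depth-3 nested tree vs exhaustive path enumeration
  leafs <- list(c(A = 1, B = 0, C = 0), c(A = 0, B = 1, C = 0),
                c(A = 0, B = 0, C = 1))
  inner2 <- decision_node("L2", list(
    tree_branch(0.25, cost = 10, child = leafs[[1]]),
    tree_branch(0.75, cost = 20, child = leafs[[2]])
  ))
  inner1 <- decision_node("L1", list(
    tree_branch(0.4, cost = 5, child = inner2),
    tree_branch(0.6, cost = 0, child = leafs[[3]])
  ))
  root <- decision_node("root", list(
    tree_branch(1 / 3, cost = 100, child = inner1),
    tree_branch(2 / 3, cost = 50, child = leafs[[1]])
  ))
  rb3 <- rollback_tree(root)
  # enumerate the four root-to-terminal paths by hand
  paths <- list(
    list(p = 1 / 3 * 0.4 * 0.25, cost = 100 + 5 + 10, entry = leafs[[1]]),
    list(p = 1 / 3 * 0.4 * 0.75, cost = 100 + 5 + 20, entry = leafs[[2]]),
    list(p = 1 / 3 * 0.6, cost = 100, entry = leafs[[3]]),
    list(p = 2 / 3, cost = 50, entry = leafs[[1]])
  )
  exp_entry <- Reduce(`+`, lapply(paths, function(x) x$p * x$entry))
  exp_cost <- sum(vapply(paths, function(x) x$p * x$cost, numeric(1)))
  expect_equal(rb3$entry, exp_entry, tolerance = 1e-12)
  expect_equal(rb3$upfront_cost, exp_cost, tolerance = 1e-12)

  # validation errors name the offending node
  bad <- decision_node("broken", list(
    tree_branch(0.6, child = c(A = 1)),
    tree_branch(0.6, child = c(A = 1))
  ))
  expect_error(rollback_tree(bad), "broken")
  mixed_states <- decision_node("root", list(
    tree_branch(0.5, child = c(A = 1)),
    tree_branch(0.5, child = c(B = 1))
  ))
  expect_error(rollback_tree(mixed_states), "different state sets")
})
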