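test_that("distribution specs validate arguments and report analytic means", {
  expect_error(dist_spec("beta", 0, 2), "invalid arguments")
  expect_error(dist_spec("gamma", 2), "2 arguments")
  expect_error(dist_spec("triangular", 1, 0, 2), "invalid arguments")
  expect_equal(dist_mean(dist_spec("beta", 2, 6)), 0.25)
  expect_equal(dist_mean(dist_spec("gamma", 4, 250)), 1000)
  expect_equal(dist_mean(dist_spec("lognormal", 0, 0.5)), exp(0.125))
  expect_equal(dist_mean(dist_spec("uniform", 2, 8)), 5)
  expect_equal(dist_mean(dist_spec("triangular", 0, 3, 6)), 3)
})

test_that("triangular inverse-CDF sampling has the right support and mean", {
  set.seed(42)
  x <- sample_dist(dist_spec("triangular", 2, 5, 11), 20000)
  expect_true(all(x >= 2 & x <= 11))
  # mean (2+5+11)/3 = 6, var = (4+25+121-10-55-22)/18 = 3.5
  se <- sqrt(3.5 / 20000)
  expect_lt(abs(mean(x) - 6), 3 * se)
})

test_that("moment-matching constructors hit their targets", {
  b <- beta_from_moments(0.3, 0.05)
  expect_equal(dist_mean(b), 0.3, tolerance = 1e-12)
  expect_equal(b$args[1] * b$args[2] / ((sum(b$args))^2 * (sum(b$args) + 1)),
               0.05^2, tolerance = 1e-12)
  expect_error(beta_from_moments(0.5, 0.6), "too large")

  g <- gamma_from_moments(1200, 300)
  expect_equal(dist_mean(g), 1200, tolerance = 1e-12)
  expect_equal(sqrt(g$args[1]) * g$args[2], 300, tolerance = 1e-12)

  ln <- lognormal_from_interval(0.5, 0.11, 1.0)
  expect_equal(exp(ln$args[1]), 0.5)
  expect_equal(stats::qlnorm(0.975, ln$args[1], ln$args[2]) /
                 stats::qlnorm(0.025, ln$args[1], ln$args[2]),
               1.0 / 0.11, tolerance = 1e-9)
})

test_that("one-way analysis matches closed form and brute-force re-evaluation", {
  ps <- linear_toy_params()
  tor <- owsa(linear_toy_builder, ps, outcome = "delta_cost")
  expect_s3_class(tor, "tornado")
  # delta_cost = price*n - offset: |coef| * (high - low)
  expect_equal(tor$width[tor$name == "price"], 100 * (20 - 10))
  expect_equal(tor$width[tor$name == "offset"], 1 * (600 - 400))
  expect_equal(tor$width[tor$name == "qaly_gain"], 0)   # inert for delta_cost
  expect_equal(tor$width[tor$name == "n_patients"], 0)  # degenerate range
  expect_true(all(diff(tor$width) <= 0))                # sorted descending

  # brute-force 2-point re-evaluation oracle
  base <- base_values(ps)
  for (i in seq_len(nrow(ps))) {
    for (bound in c("low", "high")) {
      v <- base
      v[ps$name[i]] <- ps[[bound]][i]
      want <- linear_toy_builder(v)$delta_cost
      col <- paste0("outcome_", bound)
      expect_equal(tor[[col]][tor$name == ps$name[i]], want)
    }
  }

  failing <- function(v) {
    if (v[["price"]] < 11) stop("boom")
    linear_toy_builder(v)
  }
  expect_error(owsa(failing, ps), "'price' at its low bound")
})

test_that("scenario evaluation applies overrides simultaneously without touching the base set", {
  ps <- linear_toy_params()
  expect_equal(scenario(linear_toy_builder, ps)$delta_cost,
               linear_toy_builder(base_values(ps))$delta_cost)
  # zeroing the offset raises delta_cost by exactly its contribution
  s1 <- scenario(linear_toy_builder, ps, list(offset = 0))
  expect_equal(s1$delta_cost, scenario(linear_toy_builder, ps)$delta_cost + 500)
  # simultaneous overrides equal a hand-edited rebuild
  s2 <- scenario(linear_toy_builder, ps, list(price = 12, qaly_gain = 0.2))
  v <- base_values(ps); v["price"] <- 12; v["qaly_gain"] <- 0.2
  expect_equal(s2$delta_cost, linear_toy_builder(v)$delta_cost)
  expect_equal(s2$delta_qaly, 0.2)
  expect_error(scenario(linear_toy_builder, ps, list(nope = 1)), "nope")
  expect_equal(base_values(ps)[["price"]], 15)  # base set untouched
})

test_that("PSA is seed-reproducible and degenerate distributions recover the base case", {
  ps <- linear_toy_params()
  s1 <- psa(linear_toy_builder, ps, n = 200, seed = 11)
  s2 <- psa(linear_toy_builder, ps, n = 200, seed = 11)
  expect_identical(s1$draws, s2$draws)
  expect_identical(s1$param_draws, s2$param_draws)
  s3 <- psa(linear_toy_builder, ps, n = 200, seed = 12)
  expect_false(identical(s1$draws, s3$draws))

  degen <- parameter_set(
    param("price", "cost", 15, dist = dist_spec("uniform", 15, 15)),
    param("n_patients", "count", 100, dist = dist_spec("uniform", 100, 100)),
    param("offset", "cost", 500, dist = dist_spec("uniform", 500, 500)),
    param("qaly_gain", "count", 0.1, dist = dist_spec("uniform", 0.1, 0.1))
  )
  sd <- psa(linear_toy_builder, degen, n = 25, seed = 1)
  base_dc <- linear_toy_builder(base_values(degen))$delta_cost
  expect_true(all(sd$draws$delta_cost == base_dc))

  nodist <- parameter_set(param("price", "cost", 15, 10, 20),
                          param("n_patients", "count", 100),
                          param("offset", "cost", 500),
                          param("qaly_gain", "count", 0.1))
  expect_error(psa(linear_toy_builder, nodist, n = 5, seed = 1,
                   on_missing_dist = "error"), "without a distribution")
  held <- psa(linear_toy_builder, nodist, n = 5, seed = 1)
  expect_setequal(held$held, c("price", "n_patients", "offset", "qaly_gain"))
})

test_that("CEAC counts strictly positive net benefit and hits its endpoints", {
  s <- manual_psa_samples(delta_cost = c(-10, 10, 10),
                          delta_qaly = c(0.1, 0.1, -0.1))
  expect_equal(ceac(s, 0)$probability, 1 / 3)
  expect_equal(ceac(s, 200)$probability, 2 / 3)
  expect_error(ceac(s, numeric(0)), "empty")

  dominant <- manual_psa_samples(delta_cost = c(-5, -1), delta_qaly = c(0.2, 0.1))
  expect_true(all(ceac(dominant, c(0, 1e4, 1e5))$probability == 1))

  # lambda = 0: fraction of cost-saving draws; lambda huge: fraction QALY-gaining
  set.seed(3)
  s2 <- manual_psa_samples(delta_cost = stats::rnorm(500, 10, 40),
                           delta_qaly = stats::rnorm(500, 0.05, 0.1))
  cc <- ceac(s2, c(0, 1e12))
  expect_equal(cc$probability[1], mean(s2$draws$delta_cost < 0))
  expect_equal(cc$probability[2], mean(s2$draws$delta_qaly > 0))

  # tie (NMB exactly 0) counts as not cost-effective
  tie <- manual_psa_samples(delta_cost = 0, delta_qaly = 0)
  expect_equal(ceac(tie, c(0, 100))$probability, c(0, 0))
})

test_that("threshold search agrees with closed form and substitutes back consistently", {
  ps <- linear_toy_params()
  # delta_cost = price*100 - 500: sign flips at price = 5
  crit <- function(cr) cr$delta_cost < 0
  th <- threshold_search(linear_toy_builder, ps, "price", crit,
                         lower = 0, upper = 20, tol = 1e-4)
  expect_true(th$found)
  expect_equal(th$value, 5, tolerance = 1e-3)
  # substituting the boundary back puts the outcome at the criterion boundary
  at <- scenario(linear_toy_builder, ps, list(price = th$value))
  expect_lt(abs(at$delta_cost), 100 * 1e-3 + 1e-6)

  none <- threshold_search(linear_toy_builder, ps, "price", crit,
                           lower = 10, upper = 20)
  expect_false(none$found)
  expect_true(is.na(none$value))

  # dense-grid oracle at step 0.001
  grid <- seq(0, 20, by = 0.001)
  flags <- 100 * grid - 500 < 0
  oracle <- grid[max(which(flags))]
  expect_lt(abs(th$value - oracle), 0.01)
})

test_that("parameter sweeps evaluate the full model per grid point", {
  ps <- linear_toy_params()
  base_cr <- linear_toy_builder(base_values(ps))
  sw1 <- parameter_sweep(linear_toy_builder, ps, "price", 15)
  expect_equal(sw1$delta_cost, base_cr$delta_cost)

  grid <- seq(10, 20, by = 1)
  sw <- parameter_sweep(linear_toy_builder, ps, "price", grid)
  # delta_cost linear in price: second differences vanish
  expect_lt(max(abs(diff(diff(sw$delta_cost)))), 1e-10)
  expect_error(parameter_sweep(linear_toy_builder, ps, "price", c(-5, 10)),
               "outside the support")
  expect_error(parameter_sweep(linear_toy_builder, ps, "zzz", 1), "unknown")
})

test_that("NMB sign agrees with CEAC membership at any lambda", {
  set.seed(8)
  s <- manual_psa_samples(delta_cost = stats::rnorm(200, 0, 50),
                          delta_qaly = stats::rnorm(200, 0, 0.05))
  for (lam in c(0, 1000, 30000)) {
    member <- net_monetary_benefit(s$draws$delta_cost, s$draws$delta_qaly, lam) > 0
    expect_equal(ceac(s, lam)$probability, mean(member))
  }
})
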