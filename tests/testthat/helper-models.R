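# Shared fixtures: random valid Markov models and independent naive oracles.
# The oracles deliberately use explicit element-wise loops so they share no
# code path with the engine.

random_valid_model <- function(n_states, seed, time_dependent = FALSE) {
  set.seed(seed)
  make_matrix <- function() {
    m <- matrix(stats::rgamma(n_states^2, shape = 1), n_states, n_states)
    m <- m / rowSums(m)
    m[n_states, ] <- 0
    m[n_states, n_states] <- 1  # last state absorbing
    m
  }
  mats <- if (time_dependent) list(make_matrix(), make_matrix()) else make_matrix()
  states <- c(
    lapply(seq_len(n_states - 1), function(i) {
      health_state(paste0("s", i),
                   cost_per_cycle = stats::runif(1, 0, 1000),
                   utility = stats::runif(1))
    }),
    list(health_state("dead", absorbing = TRUE))
  )
  state_model(states, mats, cycle_length = 1)
}

# step-by-step occupancy propagation with explicit double loops
naive_trace <- function(mats, entry, n_cycles) {
  if (is.matrix(mats)) mats <- list(mats)
  n <- length(entry)
  out <- matrix(0, n_cycles + 1, n)
  out[1, ] <- entry
  v <- entry
  for (t in seq_len(n_cycles)) {
    m <- mats[[min(t, length(mats))]]
    w <- numeric(n)
    for (j in seq_len(n)) {
      acc <- 0
      for (i in seq_len(n)) acc <- acc + v[i] * m[i, j]
      w[j] <- acc
    }
    out[t + 1, ] <- w
    v <- w
  }
  out
}

# spreadsheet-style per-cycle outcome accumulation (end-of-cycle convention)
naive_outcomes <- function(trace, costs, utilities, alive, cycle_length,
                           rate_costs, rate_effects, upfront = 0) {
  n_cycles <- nrow(trace) - 1
  total_cost <- upfront; ly <- 0; qaly <- 0
  for (t in seq_len(n_cycles)) {
    occ <- trace[t + 1, ]
    dfc <- (1 + rate_costs)^(-(t * cycle_length))
    dfe <- (1 + rate_effects)^(-(t * cycle_length))
    total_cost <- total_cost + dfc * sum(occ * costs)
    ly <- ly + dfe * sum(occ[alive]) * cycle_length
    qaly <- qaly + dfe * sum(occ * utilities) * cycle_length
  }
  list(total_cost = total_cost, life_years = ly, qalys = qaly)
}

# linear toy comparison: delta_cost = price * n_patients - offset,
# delta_qaly = qaly_gain; used by the uncertainty-toolkit tests
linear_toy_builder <- function(v) {
  dc <- v[["price"]] * v[["n_patients"]] - v[["offset"]]
  dq <- v[["qaly_gain"]]
  compare_arms(arm_result(0, 0, 0), arm_result(dc, dq, dq))
}

linear_toy_params <- function() {
  parameter_set(
    param("price", "cost", 15, 10, 20,
          dist = dist_spec("uniform", 10, 20)),
    param("n_patients", "count", 100, 100, 100,
          dist = dist_spec("uniform", 100, 100)),
    param("offset", "cost", 500, 400, 600,
          dist = dist_spec("triangular", 400, 500, 600)),
    param("qaly_gain", "count", 0.1, 0.05, 0.15,
          dist = dist_spec("uniform", 0.05, 0.15))
  )
}

manual_psa_samples <- function(delta_cost, delta_qaly) {
  structure(
    list(draws = data.frame(delta_cost = delta_cost, delta_qaly = delta_qaly,
                            delta_ly = delta_qaly),
         param_draws = matrix(nrow = length(delta_cost), ncol = 0),
         held = character(), seed = 0L, n = length(delta_cost)),
    class = "psa_samples"
  )
}
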