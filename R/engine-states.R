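#' Define a health state
#'
#' A health state carries the per-cycle payoffs used when a cohort trace is
#' turned into economic outcomes: a cost accrued per cycle of occupancy and a
#' utility weight (per year-equivalent, so quality-adjusted life-years follow
#' from occupancy x utility x cycle length).
#'
#' @param name Short state identifier (unique within a model).
#' @param cost_per_cycle Cost accrued per cycle of occupancy (currency, >= 0).
#' @param utility Utility weight in \[0, 1\].
#' @param absorbing Logical; absorbing states (typically death) retain all
#'   occupancy once entered. Absorbing states default to zero cost and zero
#'   utility; supplying non-zero payoffs for one is allowed but must be
#'   explicit.
#' @return An object of class `health_state`.
#' @examples
#' health_state("dead", absorbing = TRUE)
#' health_state("watch_wait", cost_per_cycle = 150, utility = 0.8)
#' @export
health_state <- function(name, cost_per_cycle = 0, utility = 0, absorbing = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(utility) || utility < 0 || utility > 1) {
    stop("utility for state '", name, "' must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(cost_per_cycle) || cost_per_cycle < 0) {
    stop("cost_per_cycle for state '", name, "' must be >= 0", call. = FALSE)
  }
  structure(
    list(name = name, cost_per_cycle = cost_per_cycle,
         utility = utility, absorbing = isTRUE(absorbing)),
    class = "health_state"
  )
}

#' Assemble a Markov state-transition model
#'
#' Combines an ordered set of health states with a per-cycle transition
#' matrix (or a list of matrices for time-dependent transitions, one per
#' cycle, recycled from the last entry if the horizon is longer).
#'
#' Validation enforces the usual cohort-model invariants: probabilities in
#' \[0, 1\], rows summing to one (rows off by less than `tol` are
#' renormalised; larger deviations are an error), at least one absorbing
#' state, and identity rows for absorbing states.
#'
#' @param states List of [health_state()] objects.
#' @param transitions Square numeric matrix indexed (from, to) in state
#'   order, or a list of such matrices for time-dependent models.
#' @param cycle_length Cycle length in years (default 1/12, a monthly cycle).
#' @param tol Row-sum tolerance; deviations below it are silently
#'   renormalised, above it rejected.
#' @return An object of class `state_model`.
#' @examples
#' sm <- state_model(
#'   states = list(
#'     health_state("alive", cost_per_cycle = 100, utility = 1),
#'     health_state("dead", absorbing = TRUE)
#'   ),
#'   transitions = matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE),
#'   cycle_length = 1
#' )
#' @export
state_model <- function(states, transitions, cycle_length = 1 / 12, tol = 1e-9) {
  stopifnot(is.list(states), length(states) >= 2L)
  if (!all(vapply(states, inherits, logical(1), "health_state"))) {
    stop("states must be a list of health_state objects", call. = FALSE)
  }
  nm <- vapply(states, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate state names: ",
                              paste(nm[duplicated(nm)], collapse = ", "), call. = FALSE)
  absorbing <- vapply(states, `[[`, logical(1), "absorbing")
  if (!any(absorbing)) stop("model must contain at least one absorbing state", call. = FALSE)
  if (!is.numeric(cycle_length) || cycle_length <= 0) {
    stop("cycle_length must be positive", call. = FALSE)
  }

  mats <- if (is.matrix(transitions)) list(transitions) else transitions
  if (!is.list(mats) || !all(vapply(mats, is.matrix, logical(1)))) {
    stop("transitions must be a matrix or a list of matrices", call. = FALSE)
  }
  n <- length(states)
  mats <- lapply(seq_along(mats), function(k) {
    m <- mats[[k]]
    if (!all(dim(m) == c(n, n))) {
      stop("transition matrix ", k, " is not ", n, "x", n, call. = FALSE)
    }
    if (any(m < 0 | m > 1)) {
      stop("transition matrix ", k, " has probabilities outside [0, 1]", call. = FALSE)
    }
    rs <- rowSums(m)
    bad <- abs(rs - 1) > tol
    if (any(bad)) {
      stop("transition matrix ", k, ": rows ", paste(which(bad), collapse = ", "),
           " (", paste(nm[bad], collapse = ", "), ") do not sum to 1 within ", tol,
           call. = FALSE)
    }
    m <- m / rs  # renormalise sub-tolerance drift
    for (i in which(absorbing)) {
      if (abs(m[i, i] - 1) > tol || any(abs(m[i, -i]) > tol)) {
        stop("absorbing state '", nm[i], "' must have an identity transition row",
             call. = FALSE)
      }
      m[i, ] <- 0; m[i, i] <- 1
    }
    dimnames(m) <- list(nm, nm)
    m
  })

  structure(
    list(states = states, state_names = nm, absorbing = absorbing,
         transitions = mats, time_dependent = length(mats) > 1L,
         cycle_length = cycle_length,
         cost_per_cycle = stats::setNames(vapply(states, `[[`, numeric(1), "cost_per_cycle"), nm),
         utility = stats::setNames(vapply(states, `[[`, numeric(1), "utility"), nm)),
    class = "state_model"
  )
}

#' @export
print.state_model <- function(x, ...) {
  cat("Markov state-transition model:", length(x$states), "states,",
      if (x$time_dependent) paste(length(x$transitions), "time-dependent matrices,")
      else "constant transitions,",
      "cycle length", format(x$cycle_length), "years\n")
  cat("  states:", paste0(x$state_names, ifelse(x$absorbing, "*", ""), collapse = ", "),
      "(* absorbing)\n")
  invisible(x)
}

#' Plan the simulated time horizon and discounting
#'
#' @param horizon_years Total simulated time in years; must be a positive
#'   integer multiple of the cycle length.
#' @param cycle_length_years Cycle length in years.
#' @param discount_costs,discount_effects Annual discount rates in \[0, 1).
#' @param half_cycle_correction Logical; if `TRUE` (default) per-cycle
#'   payoffs use the trapezoidal mean of start- and end-of-cycle occupancy,
#'   discounted at the cycle midpoint.
#' @return An object of class `cycle_plan`.
#' @examples
#' cycle_plan(40, 1 / 12, discount_costs = 0.03, discount_effects = 0.03)
#' @export
cycle_plan <- function(horizon_years, cycle_length_years = 1 / 12,
                       discount_costs = 0.03, discount_effects = 0.03,
                       half_cycle_correction = TRUE) {
  stopifnot(horizon_years > 0, cycle_length_years > 0)
  n_cycles <- horizon_years / cycle_length_years
  if (abs(n_cycles - round(n_cycles)) > 1e-8) {
    stop("horizon_years (", horizon_years, ") must be an integer multiple of ",
         "cycle_length_years (", cycle_length_years, ")", call. = FALSE)
  }
  for (r in c(discount_costs, discount_effects)) {
    if (!is.numeric(r) || r < 0 || r >= 1) {
      stop("discount rates must lie in [0, 1)", call. = FALSE)
    }
  }
  structure(
    list(horizon_years = horizon_years,
         cycle_length_years = cycle_length_years,
         n_cycles = as.integer(round(n_cycles)),
         discount_costs = discount_costs,
         discount_effects = discount_effects,
         half_cycle_correction = isTRUE(half_cycle_correction)),
    class = "cycle_plan"
  )
}

#' Continuous-time discount factor
#'
#' Present-value weight `1 / (1 + rate)^t` for a payoff accruing at time
#' `t` years; equals 1 at `t = 0` or `rate = 0`.
#'
#' @param t Time in years (>= 0); vectorised.
#' @param rate Annual discount rate in \[0, 1).
#' @return Numeric vector of discount factors.
#' @examples
#' discount_factor(2, 0.03)  # 1 / 1.0609
#' @export
discount_factor <- function(t, rate) {
  stopifnot(all(t >= 0), rate >= 0, rate < 1)
  (1 + rate)^(-t)
}

#' Convert a hazard ratio to an adjusted per-cycle probability
#'
#' Applies a hazard ratio on the rate scale: the per-cycle probability `p`
#' is converted to a cumulative hazard `-log(1 - p)`, multiplied by `hr`,
#' and converted back, giving `1 - (1 - p)^hr`. This is the standard way to
#' carry a published hazard ratio (e.g. for time to next treatment under an
#' early-treatment strategy) into a discrete-time transition probability.
#'
#' @param p Per-cycle probability in \[0, 1); vectorised.
#' @param hr Hazard ratio (> 0).
#' @return Adjusted per-cycle probability in \[0, 1).
#' @examples
#' hr_adjust_probability(0.2, 1)     # unchanged
#' hr_adjust_probability(0.2, 0.11)  # strongly delayed event
#' @export
hr_adjust_probability <- function(p, hr) {
  stopifnot(length(hr) == 1L, is.numeric(hr))
  if (hr <= 0) stop("hazard ratio must be > 0", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (any(p == 1) && hr != 1) {
    stop("p = 1 has no finite hazard; hazard-ratio adjustment undefined", call. = FALSE)
  }
  if (hr == 1) return(p)  # exact fixed point; 1 - (1 - p) loses a ulp
  1 - (1 - p)^hr
}

#' Run a cohort through a Markov model
#'
#' Propagates an entry distribution through the model's per-cycle transition
#' matrices, producing the fractional state occupancy at every cycle
#' (row 0 = entry). For time-dependent models, matrix `t` governs the
#' transition from cycle `t - 1` to cycle `t`; if fewer matrices than cycles
#' are supplied the last matrix is reused.
#'
#' @param model A [state_model()].
#' @param entry Named (or positional) entry distribution over the model's
#'   states; must sum to 1 within `1e-9`.
#' @param plan A [cycle_plan()]; its cycle length must match the model's.
#' @return A `cohort_trace`: a `(n_cycles + 1) x n_states` matrix of
#'   occupancy fractions with the model attached as an attribute.
#' @examples
#' sm <- state_model(
#'   list(health_state("alive", utility = 1), health_state("dead", absorbing = TRUE)),
#'   matrix(c(0.5, 0.5, 0, 1), 2, 2, byrow = TRUE), cycle_length = 1
#' )
#' run_cohort(sm, c(alive = 1, dead = 0), cycle_plan(2, 1))
#' @export
run_cohort <- function(model, entry, plan) {
  stopifnot(inherits(model, "state_model"), inherits(plan, "cycle_plan"))
  if (abs(plan$cycle_length_years - model$cycle_length) > 1e-12) {
    stop("plan cycle length (", plan$cycle_length_years,
         ") does not match model cycle length (", model$cycle_length, ")",
         call. = FALSE)
  }
  n <- length(model$state_names)
  if (!is.null(names(entry))) {
    if (!setequal(names(entry), model$state_names)) {
      stop("entry distribution names do not match model states", call. = FALSE)
    }
    entry <- entry[model$state_names]
  }
  if (length(entry) != n) stop("entry distribution has wrong length", call. = FALSE)
  if (any(entry < 0) || abs(sum(entry) - 1) > 1e-9) {
    stop("entry distribution must be non-negative and sum to 1", call. = FALSE)
  }
  entry <- entry / sum(entry)

  n_cycles <- plan$n_cycles
  occ <- matrix(0, nrow = n_cycles + 1L, ncol = n,
                dimnames = list(0:n_cycles, model$state_names))
  occ[1L, ] <- entry
  mats <- model$transitions
  k <- length(mats)
  v <- entry
  for (t in seq_len(n_cycles)) {
    v <- as.numeric(v %*% mats[[min(t, k)]])
    occ[t + 1L, ] <- v
  }
  structure(occ, class = c("cohort_trace", "matrix", "array"), model = attr(model, "name"))
}

#' Build a decision node
#'
#' A decision/chance node whose branches each carry a probability, an
#' immediate cost payoff, and either a child node or a terminal entry
#' distribution over the Markov model's states.
#'
#' @param label Node label (used in validation error messages).
#' @param branches List of branches created with [tree_branch()].
#' @return A `decision_node`.
#' @seealso [rollback_tree()]
#' @export
decision_node <- function(label, branches) {
  stopifnot(is.character(label), is.list(branches), length(branches) >= 1L)
  structure(list(label = label, branches = branches), class = "decision_node")
}

#' @rdname decision_node
#' @param probability Branch probability; probabilities at each node must sum to 1.
#' @param cost Immediate cost incurred on taking this branch.
#' @param child Either another [decision_node()] or a named numeric terminal
#'   entry distribution over Markov states.
#' @export
tree_branch <- function(probability, cost = 0, child) {
  stopifnot(is.numeric(probability), probability >= 0, probability <= 1)
  structure(list(probability = probability, cost = cost, child = child),
            class = "tree_branch")
}

#' Roll back a decision tree to an entry distribution and expected cost
#'
#' Probability-weights every root-to-terminal path, accumulating branch cost
#' payoffs along the way, and returns the resulting entry distribution over
#' Markov states together with the expected upfront cost. This is the
#' classical expected-value rollback used when a short-term decision tree
#' (e.g. infection occurrence and timing of detection) feeds a long-term
#' state-transition model.
#'
#' @param root A [decision_node()].
#' @return List with `entry` (named distribution summing to 1) and
#'   `upfront_cost` (expected immediate cost).
#' @examples
#' tree <- decision_node("detect", list(
#'   tree_branch(0.5, cost = 100, child = c(A = 1, B = 0)),
#'   tree_branch(0.5, cost = 300, child = c(A = 0, B = 1))
#' ))
#' rollback_tree(tree)  # entry (0.5, 0.5), expected cost 200
#' @export
rollback_tree <- function(root) {
  stopifnot(inherits(root, "decision_node"))
  res <- rollback_node(root)
  res$entry <- res$entry / sum(res$entry)
  res
}

rollback_node <- function(node) {
  probs <- vapply(node$branches, `[[`, numeric(1), "probability")
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("branch probabilities at node '", node$label, "' sum to ",
         format(sum(probs), digits = 12), ", not 1", call. = FALSE)
  }
  entry <- NULL
  cost <- 0
  for (b in node$branches) {
    if (inherits(b$child, "decision_node")) {
      sub <- rollback_node(b$child)
      e <- sub$entry
      cost <- cost + b$probability * (b$cost + sub$upfront_cost)
    } else {
      e <- b$child
      if (is.null(names(e)) || !is.numeric(e)) {
        stop("terminal of node '", node$label,
             "' must be a named numeric entry distribution", call. = FALSE)
      }
      if (any(e < 0) || abs(sum(e) - 1) > 1e-9) {
        stop("terminal distribution at node '", node$label, "' must sum to 1",
             call. = FALSE)
      }
      cost <- cost + b$probability * b$cost
    }
    if (is.null(entry)) {
      entry <- b$probability * e
    } else {
      if (!setequal(names(entry), names(e))) {
        stop("terminals under node '", node$label,
             "' reference different state sets", call. = FALSE)
      }
      entry <- entry + b$probability * e[names(entry)]
    }
  }
  list(entry = entry, upfront_cost = cost)
}
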