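#' Define a model parameter
#'
#' A parameter carries a base (most likely) value, a low/high range for
#' one-way sensitivity analysis, an optional sampling distribution for
#' probabilistic sensitivity analysis, a kind (which constrains its
#' support), and a source tag recording where the value came from.
#'
#' @param name Parameter name (unique within a set).
#' @param kind One of `"probability"`, `"utility"`, `"cost"`,
#'   `"hazard_ratio"`, `"rate"`, `"count"`.
#' @param base Base-case value; must satisfy `low <= base <= high` and the
#'   kind's support (probabilities/utilities in \[0, 1\], costs >= 0,
#'   hazard ratios > 0).
#' @param low,high Range for one-way analysis; default to `base` (a fixed
#'   parameter).
#' @param dist Optional [dist_spec()] used by [psa()].
#' @param source_tag Provenance: `"literature"`, `"guideline"`, `"expert"`
#'   or `"assumption"`.
#' @return One-row data frame; combine rows with [parameter_set()].
#' @export
param <- function(name, kind, base, low = base, high = base,
                  dist = NULL, source_tag = "assumption") {
  kind <- match.arg(kind, c("probability", "utility", "cost",
                            "hazard_ratio", "rate", "count"))
  if (!(low <= base && base <= high)) {
    stop("parameter '", name, "': require low <= base <= high", call. = FALSE)
  }
  support <- kind_support(kind)
  for (v in c(low, base, high)) {
    if (v < support[1] || v > support[2]) {
      stop("parameter '", name, "' (", kind, "): value ", v,
           " outside support [", support[1], ", ", support[2], "]", call. = FALSE)
    }
  }
  if (!is.null(dist) && !inherits(dist, "dist_spec")) {
    stop("dist must be a dist_spec or NULL", call. = FALSE)
  }
  data.frame(
    name = name, kind = kind, base = base, low = low, high = high,
    dist_family = if (is.null(dist)) NA_character_ else dist$family,
    dist_arg1 = if (is.null(dist)) NA_real_ else dist$args[1],
    dist_arg2 = if (is.null(dist)) NA_real_ else dist$args[2],
    dist_arg3 = if (is.null(dist) || length(dist$args) < 3) NA_real_ else dist$args[3],
    source_tag = source_tag,
    stringsAsFactors = FALSE
  )
}

kind_support <- function(kind) {
  switch(kind,
         probability = c(0, 1),
         utility = c(0, 1),
         cost = c(0, Inf),
         hazard_ratio = c(1e-12, Inf),
         rate = c(0, Inf),
         count = c(0, Inf))
}

#' Assemble a parameter set
#'
#' Binds [param()] rows into the single source of truth for a model's
#' numbers. Parameter sets are plain data frames (class `parameter_set`)
#' with columns `name`, `kind`, `base`, `low`, `high`, `dist_family`,
#' `dist_arg1..3`, `source_tag`.
#'
#' @param ... [param()] rows or data frames with the same columns.
#' @return A `parameter_set` data frame.
#' @examples
#' ps <- parameter_set(
#'   param("p_progress", "probability", 0.02, 0.01, 0.04),
#'   param("c_drug", "cost", 5084, 2542, 7626)
#' )
#' @export
parameter_set <- function(...) {
  rows <- list(...)
  df <- if (length(rows) == 0) {
    param("..placeholder", "count", 0)[0, ]
  } else {
    do.call(rbind, rows)
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate parameter names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("parameter_set", "data.frame")
  df
}

#' Extract base-case values from a parameter set
#'
#' @param params A [parameter_set()].
#' @return Named numeric vector of base values, the form every model
#'   builder consumes.
#' @export
base_values <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  stats::setNames(params$base, params$name)
}

#' Apply named overrides to a value vector
#'
#' @param values Named numeric vector (e.g. from [base_values()]).
#' @param overrides Named list/vector of replacement values; every name must
#'   already exist in `values`.
#' @return The vector with overrides applied.
#' @export
apply_overrides <- function(values, overrides) {
  overrides <- unlist(overrides)
  if (length(overrides) == 0) return(values)
  unknown <- setdiff(names(overrides), names(values))
  if (length(unknown)) {
    stop("unknown parameter name(s) in overrides: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  values[names(overrides)] <- overrides
  values
}

#' Accumulate discounted costs, life-years and QALYs from a cohort trace
#'
#' Each cycle contributes occupancy-weighted payoffs: per-state costs, time
#' alive (occupancy of non-absorbing states x cycle length) and
#' quality-adjusted time (utility-weighted occupancy x cycle length), each
#' discounted to present value. With the half-cycle correction enabled in
#' the plan, cycle payoffs use the trapezoidal mean of the occupancy at the
#' start and end of the cycle, discounted at the cycle midpoint; without it,
#' end-of-cycle occupancy discounted at end-of-cycle time is used.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param model The [state_model()] that produced it.
#' @param plan The [cycle_plan()] used.
#' @param upfront_cost Expected immediate cost incurred before cycle 1
#'   (e.g. from [rollback_tree()]); undiscounted.
#' @return An `arm_result` with `total_cost`, `life_years`, `qalys`.
#' @export
accumulate_outcomes <- function(trace, model, plan, upfront_cost = 0) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(model, "state_model"),
            inherits(plan, "cycle_plan"))
  if (ncol(trace) != length(model$state_names) ||
      !identical(colnames(trace), model$state_names)) {
    stop("trace columns do not match model states", call. = FALSE)
  }
  n_cycles <- nrow(trace) - 1L
  cl <- plan$cycle_length_years
  if (n_cycles == 0L) {
    return(new_arm_result(upfront_cost, 0, 0))
  }

  occ_end <- trace[-1L, , drop = FALSE]
  if (plan$half_cycle_correction) {
    occ_use <- (trace[-nrow(trace), , drop = FALSE] + occ_end) / 2
    times <- (seq_len(n_cycles) - 0.5) * cl
  } else {
    occ_use <- occ_end
    times <- seq_len(n_cycles) * cl
  }
  df_c <- discount_factor(times, plan$discount_costs)
  df_e <- discount_factor(times, plan$discount_effects)

  cost_per_cycle <- as.numeric(occ_use %*% model$cost_per_cycle)
  qaly_per_cycle <- as.numeric(occ_use %*% model$utility) * cl
  alive_per_cycle <- rowSums(occ_use[, !model$absorbing, drop = FALSE]) * cl

  new_arm_result(
    total_cost = upfront_cost + sum(df_c * cost_per_cycle),
    life_years = sum(df_e * alive_per_cycle),
    qalys = sum(df_e * qaly_per_cycle)
  )
}

new_arm_result <- function(total_cost, life_years, qalys) {
  structure(list(total_cost = total_cost, life_years = life_years, qalys = qalys),
            class = "arm_result")
}

#' Construct an arm result directly
#'
#' Used when per-arm totals come from an external source (e.g. a published
#' results table) rather than from [accumulate_outcomes()].
#'
#' @param total_cost,life_years,qalys Discounted per-arm totals.
#' @return An `arm_result`.
#' @export
arm_result <- function(total_cost, life_years = NA_real_, qalys = NA_real_) {
  new_arm_result(total_cost, life_years, qalys)
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("arm result: cost %.2f | LY %.4f | QALY %.4f\n",
              x$total_cost, x$life_years, x$qalys))
  invisible(x)
}

#' Weighted mixture of arm results
#'
#' Cohort models are linear in the entry cohort, so the outcome of a cohort
#' split across pathways (e.g. high-risk patients treated early, the rest
#' managed as usual) is the probability-weighted mixture of the pathway
#' outcomes.
#'
#' @param results List of `arm_result`s.
#' @param weights Non-negative weights summing to 1.
#' @return An `arm_result`.
#' @export
mix_arms <- function(results, weights) {
  stopifnot(length(results) == length(weights), all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9)
  # computed as x1 + sum_{i>1} w_i (x_i - x1): algebraically the weighted
  # mean (weights sum to 1) but exact when all pathways coincide
  mix1 <- function(field) {
    x <- vapply(results, `[[`, numeric(1), field)
    x[1] + sum(weights[-1] * (x[-1] - x[1]))
  }
  new_arm_result(mix1("total_cost"), mix1("life_years"), mix1("qalys"))
}

#' Compare an intervention arm against a comparator
#'
#' Computes incremental cost, life-years and QALYs (intervention minus
#' comparator, exactly), ICERs per life-year and per QALY where the effect
#' denominator is non-zero (`NA` otherwise, never a division by zero), and
#' a dominance label: `"dominant"` (cheaper and more effective),
#' `"dominated"` (costlier and less effective) or `"trade-off"`.
#'
#' @param comparator,intervention `arm_result`s computed under the same plan.
#' @return A `comparison_result`.
#' @examples
#' compare_arms(arm_result(103947, 11.18, 8.57), arm_result(193932, 11.51, 8.69))
#' @export
compare_arms <- function(comparator, intervention) {
  stopifnot(inherits(comparator, "arm_result"), inherits(intervention, "arm_result"))
  d_cost <- intervention$total_cost - comparator$total_cost
  d_ly <- intervention$life_years - comparator$life_years
  d_qaly <- intervention$qalys - comparator$qalys
  label <- if (!is.na(d_qaly) && d_cost < 0 && d_qaly > 0) "dominant"
           else if (!is.na(d_qaly) && d_cost > 0 && d_qaly < 0) "dominated"
           else "trade-off"
  structure(
    list(comparator = comparator, intervention = intervention,
         delta_cost = d_cost, delta_ly = d_ly, delta_qaly = d_qaly,
         icer_per_ly = if (is.na(d_ly) || d_ly == 0) NA_real_ else d_cost / d_ly,
         icer_per_qaly = if (is.na(d_qaly) || d_qaly == 0) NA_real_ else d_cost / d_qaly,
         dominance_label = label),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(render_comparison_report(x), sep = "\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = lambda * delta_qaly - delta_cost`: positive iff the intervention
#' is cost-effective at willingness-to-pay `lambda` per QALY. Vectorised
#' over all arguments.
#'
#' @param delta_cost,delta_qaly Incremental cost and QALYs.
#' @param lambda Willingness-to-pay per QALY (>= 0).
#' @return Net monetary benefit in currency units.
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, lambda) {
  stopifnot(all(lambda >= 0))
  lambda * delta_qaly - delta_cost
}

#' Headroom for a technology's price
#'
#' `headroom = N + lambda * Q`, where `N` is the saving realised when the
#' technology's own cost is set to zero, `lambda` the willingness-to-pay
#' per QALY and `Q` the QALYs gained. It bounds the price at which the
#' technology (including validation and implementation costs) can still be
#' worthwhile to a payer.
#'
#' @param N Savings at zero technology cost (currency).
#' @param lambda Willingness-to-pay per QALY (>= 0).
#' @param Q Health effects gained (QALYs).
#' @return A `headroom_result` with fields `N`, `lambda`, `Q`, `headroom`.
#' @examples
#' headroom(N = 886, lambda = 20000, Q = 0.06)
#' @export
headroom <- function(N, lambda, Q) {
  stopifnot(lambda >= 0)
  structure(list(N = N, lambda = lambda, Q = Q, headroom = N + lambda * Q),
            class = "headroom_result")
}

#' @export
print.headroom_result <- function(x, ...) {
  cat(sprintf("headroom = N + lambda * Q = %.2f + %.0f * %.4f = %.2f\n",
              x$N, x$lambda, x$Q, x$headroom))
  invisible(x)
}
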