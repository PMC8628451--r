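#' Specify a sampling distribution for a parameter
#'
#' Supported families and their arguments:
#' * `beta(alpha, beta)` — probabilities and utilities;
#' * `gamma(shape, scale)` — costs and other non-negative quantities;
#' * `lognormal(meanlog, sdlog)` — hazard ratios;
#' * `uniform(min, max)` — fallback;
#' * `triangular(min, mode, max)`.
#'
#' @param family Distribution family name.
#' @param ... Family arguments, in the order listed above.
#' @return A `dist_spec`.
#' @export
dist_spec <- function(family, ...) {
  family <- match.arg(family, c("beta", "gamma", "lognormal", "uniform", "triangular"))
  args <- c(...)
  n_expected <- if (family == "triangular") 3L else 2L
  if (length(args) != n_expected) {
    stop(family, " distribution needs ", n_expected, " arguments, got ",
         length(args), call. = FALSE)
  }
  ok <- switch(family,
               beta = all(args > 0),
               gamma = all(args > 0),
               lognormal = args[2] > 0,
               uniform = args[1] <= args[2],
               triangular = args[1] <= args[2] && args[2] <= args[3])
  if (!ok) stop("invalid arguments for ", family, " distribution: ",
                paste(args, collapse = ", "), call. = FALSE)
  structure(list(family = family, args = unname(args)), class = "dist_spec")
}

#' @rdname dist_spec
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return `sample_dist`: `n` random draws; `dist_mean`: the analytic mean.
#' @export
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  a <- spec$args
  switch(spec$family,
         beta = stats::rbeta(n, a[1], a[2]),
         gamma = stats::rgamma(n, shape = a[1], scale = a[2]),
         lognormal = stats::rlnorm(n, meanlog = a[1], sdlog = a[2]),
         uniform = stats::runif(n, a[1], a[2]),
         triangular = {
           # inverse-CDF sampling; no triangular generator in base stats
           u <- stats::runif(n)
           lo <- a[1]; mo <- a[2]; hi <- a[3]
           fc <- if (hi > lo) (mo - lo) / (hi - lo) else 0.5
           ifelse(u < fc,
                  lo + sqrt(u * (hi - lo) * (mo - lo)),
                  hi - sqrt((1 - u) * (hi - lo) * (hi - mo)))
         })
}

#' @rdname dist_spec
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  a <- spec$args
  switch(spec$family,
         beta = a[1] / (a[1] + a[2]),
         gamma = a[1] * a[2],
         lognormal = exp(a[1] + a[2]^2 / 2),
         uniform = (a[1] + a[2]) / 2,
         triangular = (a[1] + a[2] + a[3]) / 3)
}

#' Method-of-moments distribution constructors
#'
#' Build a [dist_spec()] whose mean equals `mean` and standard deviation
#' equals `sd`: `beta_from_moments` for quantities on \[0, 1\],
#' `gamma_from_moments` for non-negative quantities.
#' `lognormal_from_interval` treats `base` as the median and `(low, high)`
#' as a central 95% interval on the natural scale (the usual reading of a
#' published hazard ratio with its confidence interval).
#'
#' @param mean,sd Target moments (`sd` must be admissible for the family:
#'   for the beta, `sd^2 < mean * (1 - mean)`).
#' @return A [dist_spec()].
#' @export
beta_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1, sd > 0)
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("sd too large for a beta with mean ", mean, call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  dist_spec("beta", mean * nu, (1 - mean) * nu)
}

#' @rdname beta_from_moments
#' @export
gamma_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  dist_spec("gamma", (mean / sd)^2, sd^2 / mean)
}

#' @rdname beta_from_moments
#' @param base,low,high Median and 95% interval on the natural scale.
#' @export
lognormal_from_interval <- function(base, low, high) {
  stopifnot(low > 0, low < base, base < high)
  dist_spec("lognormal", log(base), (log(high) - log(low)) / (2 * stats::qnorm(0.975)))
}

param_dist <- function(params, i) {
  fam <- params$dist_family[i]
  if (is.na(fam)) return(NULL)
  args <- c(params$dist_arg1[i], params$dist_arg2[i], params$dist_arg3[i])
  do.call(dist_spec, c(list(fam), as.list(args[!is.na(args)])))
}

resolve_outcome <- function(outcome) {
  if (is.function(outcome)) return(outcome)
  if (is.character(outcome) && length(outcome) == 1L) {
    field <- outcome
    return(function(cr) cr[[field]])
  }
  stop("outcome must be a function(comparison_result) or a field name", call. = FALSE)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the full model once at each parameter's low and once at its
#' high bound, holding every other parameter at base, and reports the swing
#' of the selected outcome. Entries are sorted by swing, largest first —
#' the order bars appear in a tornado diagram.
#'
#' @param model_builder Function taking a named vector of parameter values
#'   and returning a `comparison_result`.
#' @param params A [parameter_set()]; every parameter needs low/high bounds.
#' @param outcome Outcome selector: a field name of `comparison_result`
#'   (default `"delta_cost"`) or a function of one.
#' @return A `tornado` data frame: `name`, `outcome_low`, `outcome_high`,
#'   `width`, with the base-case outcome as attribute `base_outcome`.
#' @export
owsa <- function(model_builder, params, outcome = "delta_cost") {
  stopifnot(inherits(params, "parameter_set"), nrow(params) >= 1L)
  f <- resolve_outcome(outcome)
  base <- base_values(params)
  base_out <- f(model_builder(base))
  eval_at <- function(name, value, bound) {
    v <- base
    v[name] <- value
    out <- tryCatch(f(model_builder(v)), error = function(e) {
      stop("model evaluation failed for parameter '", name, "' at its ", bound,
           " bound (", value, "): ", conditionMessage(e), call. = FALSE)
    })
    out
  }
  res <- data.frame(
    name = params$name,
    outcome_low = vapply(seq_len(nrow(params)), function(i)
      eval_at(params$name[i], params$low[i], "low"), numeric(1)),
    outcome_high = vapply(seq_len(nrow(params)), function(i)
      eval_at(params$name[i], params$high[i], "high"), numeric(1)),
    stringsAsFactors = FALSE
  )
  res$width <- abs(res$outcome_high - res$outcome_low)
  res <- res[order(-res$width), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "base_outcome") <- base_out
  class(res) <- c("tornado", "data.frame")
  res
}

#' Scenario analysis
#'
#' Evaluates the model once with a named set of overrides applied
#' simultaneously (e.g. a published best-case scenario); the base parameter
#' set is not modified.
#'
#' @inheritParams owsa
#' @param overrides Named list of replacement values; names must exist in
#'   `params`.
#' @return The `comparison_result` of the scenario run.
#' @export
scenario <- function(model_builder, params, overrides = list()) {
  stopifnot(inherits(params, "parameter_set"))
  model_builder(apply_overrides(base_values(params), overrides))
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter vectors — each parameter independently from its
#' [dist_spec()] — and pushes every draw through the full model. With a
#' fixed `seed` the sample set is bit-reproducible.
#'
#' @inheritParams owsa
#' @param n Number of draws (the conventional default is 1000).
#' @param seed Integer seed controlling all sampling.
#' @param on_missing_dist What to do with parameters lacking a distribution:
#'   `"hold"` keeps them at base (noted in the result), `"error"` aborts.
#' @return A `psa_samples` object: `draws` (data frame with `delta_cost`,
#'   `delta_qaly`, `delta_ly`), `param_draws` (n x p matrix), `held`
#'   (names held at base), `seed`, `n`.
#' @export
psa <- function(model_builder, params, n = 1000, seed = 1,
                on_missing_dist = c("hold", "error")) {
  stopifnot(inherits(params, "parameter_set"), n >= 1)
  on_missing_dist <- match.arg(on_missing_dist)
  base <- base_values(params)
  specs <- lapply(seq_len(nrow(params)), function(i) param_dist(params, i))
  names(specs) <- params$name
  held <- params$name[vapply(specs, is.null, logical(1))]
  if (length(held) && on_missing_dist == "error") {
    stop("parameters without a distribution: ", paste(held, collapse = ", "),
         call. = FALSE)
  }

  set.seed(seed)
  draws <- matrix(rep(base, each = n), nrow = n,
                  dimnames = list(NULL, params$name))
  for (nm in setdiff(params$name, held)) {
    draws[, nm] <- sample_dist(specs[[nm]], n)
  }

  out <- vapply(seq_len(n), function(i) {
    cr <- model_builder(draws[i, ])
    c(cr$delta_cost, cr$delta_qaly, cr$delta_ly)
  }, numeric(3))

  structure(
    list(draws = data.frame(delta_cost = out[1, ], delta_qaly = out[2, ],
                            delta_ly = out[3, ]),
         param_draws = draws, held = held, seed = seed, n = as.integer(n)),
    class = "psa_samples"
  )
}

#' @export
print.psa_samples <- function(x, ...) {
  cat("PSA sample set: n =", x$n, "draws, seed =", x$seed, "\n")
  cat(sprintf("  mean delta cost %.2f | mean delta QALY %.4f\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qaly)))
  if (length(x$held)) cat("  held at base (no distribution):",
                          paste(x$held, collapse = ", "), "\n")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' strictly positive net monetary benefit (`lambda * dQALY - dCost > 0`;
#' ties count as not cost-effective).
#'
#' @param samples A `psa_samples` object from [psa()].
#' @param lambdas Grid of willingness-to-pay values (default 0 to 200,000
#'   in steps of 1,000).
#' @return A `ceac_curve` data frame with columns `lambda`, `probability`.
#' @export
ceac <- function(samples, lambdas = seq(0, 200000, by = 1000)) {
  stopifnot(inherits(samples, "psa_samples"))
  if (length(lambdas) == 0) stop("lambda grid is empty", call. = FALSE)
  dc <- samples$draws$delta_cost
  dq <- samples$draws$delta_qaly
  prob <- vapply(lambdas, function(l) mean(l * dq - dc > 0), numeric(1))
  structure(data.frame(lambda = lambdas, probability = prob),
            class = c("ceac_curve", "data.frame"))
}

#' Threshold search on a single parameter
#'
#' Finds the parameter value at which a boolean criterion on the model
#' outcome flips (e.g. the technology price at which the intervention stops
#' saving money), by bisection between `lower` and `upper`. Monotonicity of
#' the criterion over the range is checked empirically on a coarse grid; a
#' range with no sign change returns a no-threshold result rather than an
#' error.
#'
#' @inheritParams owsa
#' @param target_param Name of the parameter to search over.
#' @param criterion Function taking a `comparison_result` and returning
#'   `TRUE`/`FALSE`.
#' @param lower,upper Search bounds; default to the parameter's low/high.
#' @param tol Absolute tolerance on the returned value (default 0.01,
#'   i.e. one cent on a price).
#' @param grid_check Number of grid points used to verify the criterion
#'   flips at most once over the range (0 disables the check).
#' @return A `threshold_result` list: `found`, `value` (boundary, `NA` if
#'   not found), `at_lower`, `at_upper` (criterion values at the bounds).
#' @export
threshold_search <- function(model_builder, params, target_param, criterion,
                             lower = NULL, upper = NULL, tol = 0.01,
                             grid_check = 9) {
  stopifnot(inherits(params, "parameter_set"))
  i <- match(target_param, params$name)
  if (is.na(i)) stop("unknown parameter: ", target_param, call. = FALSE)
  if (is.null(lower)) lower <- params$low[i]
  if (is.null(upper)) upper <- params$high[i]
  stopifnot(lower < upper)
  base <- base_values(params)
  crit_at <- function(x) {
    v <- base
    v[target_param] <- x
    isTRUE(criterion(model_builder(v)))
  }
  at_lower <- crit_at(lower)
  at_upper <- crit_at(upper)
  if (at_lower == at_upper) {
    return(structure(list(found = FALSE, value = NA_real_,
                          at_lower = at_lower, at_upper = at_upper,
                          lower = lower, upper = upper),
                     class = "threshold_result"))
  }
  if (grid_check > 2) {
    g <- vapply(seq(lower, upper, length.out = grid_check), crit_at, logical(1))
    if (sum(diff(g) != 0) > 1) {
      warning("criterion flips more than once over [", lower, ", ", upper,
              "]; bisection result may not be the unique threshold")
    }
  }
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (crit_at(mid) == at_lower) lo <- mid else hi <- mid
  }
  structure(list(found = TRUE, value = (lo + hi) / 2,
                 at_lower = at_lower, at_upper = at_upper,
                 lower = lower, upper = upper),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$found) {
    cat(sprintf("criterion flips at %.4f (searched [%.4f, %.4f])\n",
                x$value, x$lower, x$upper))
  } else {
    cat(sprintf("no threshold in [%.4f, %.4f]: criterion is %s throughout\n",
                x$lower, x$upper, x$at_lower))
  }
  invisible(x)
}

#' Sweep one parameter over a grid
#'
#' Evaluates the full model at every grid value of one parameter (all
#' others at base), e.g. the prevalence sweep behind an incremental-savings
#' curve.
#'
#' @inheritParams threshold_search
#' @param sweep_param Name of the parameter to sweep.
#' @param grid Numeric grid of values; each must lie within the parameter
#'   kind's support.
#' @return A `parameter_sweep` data frame: `value`, `delta_cost`,
#'   `delta_ly`, `delta_qaly`, `icer_per_qaly`.
#' @export
parameter_sweep <- function(model_builder, params, sweep_param, grid) {
  stopifnot(inherits(params, "parameter_set"), length(grid) >= 1L)
  i <- match(sweep_param, params$name)
  if (is.na(i)) stop("unknown parameter: ", sweep_param, call. = FALSE)
  support <- kind_support(params$kind[i])
  if (any(grid < support[1] | grid > support[2])) {
    stop("grid values outside the support of ", sweep_param,
         " (", params$kind[i], ")", call. = FALSE)
  }
  base <- base_values(params)
  rows <- lapply(grid, function(x) {
    v <- base
    v[sweep_param] <- x
    cr <- model_builder(v)
    data.frame(value = x, delta_cost = cr$delta_cost, delta_ly = cr$delta_ly,
               delta_qaly = cr$delta_qaly, icer_per_qaly = cr$icer_per_qaly)
  })
  structure(do.call(rbind, rows), class = c("parameter_sweep", "data.frame"))
}
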