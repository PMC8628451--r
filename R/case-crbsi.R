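#' Illustrative parameter set for the ICU CRBSI early-detection case
#'
#' Catheter-related bloodstream infections (CRBSI) in intensive care are
#' treated by catheter removal and antibiotics in both arms; what the
#' analytics change is the timing of detection. Early detection lowers
#' ICU mortality and shortens the infection-attributable ICU stay. The
#' technology is priced per ICU bed and spread over the patients a bed
#' serves per year.
#'
#' Values are illustrative (`source_tag = "assumption"`), chosen to sit in
#' a clinically plausible range for a European ICU; the main-text results
#' report only the resulting per-patient benefit, not the inputs.
#'
#' @return A [parameter_set()] consumed by [build_crbsi_model()].
#' @export
crbsi_parameter_set <- function() {
  parameter_set(
    param("p_crbsi", "probability", 0.05, 0.01, 0.15,
          dist = beta_from_moments(0.05, 0.015)),
    # ICU mortality by infection status and detection timing
    param("p_death_icu_nocrbsi", "probability", 0.10, 0.05, 0.20,
          dist = beta_from_moments(0.10, 0.02)),
    param("p_death_icu_late", "probability", 0.30, 0.20, 0.40,
          dist = beta_from_moments(0.30, 0.05)),
    param("p_death_icu_early", "probability", 0.20, 0.10, 0.30,
          dist = beta_from_moments(0.20, 0.05)),
    # ICU length of stay (days)
    param("los_icu_base", "count", 8, 5, 12,
          dist = gamma_from_moments(8, 1.5)),
    param("los_extra_late", "count", 12, 6, 18,
          dist = gamma_from_moments(12, 3)),
    param("los_extra_early", "count", 5, 2, 8,
          dist = gamma_from_moments(5, 1.5)),
    # unit costs
    param("c_icu_day", "cost", 2531, 1500, 3500,
          dist = gamma_from_moments(2531, 400)),
    param("c_antibiotics", "cost", 400, 200, 800,
          dist = gamma_from_moments(400, 120)),
    param("c_ward_cycle", "cost", 3000, 1500, 4500,
          dist = gamma_from_moments(3000, 600)),
    # technology pricing: per bed per year, spread over bed throughput
    param("price_per_bed", "cost", 0, 0, 50000),
    param("patients_per_bed", "count", 21.7, 10, 40,
          dist = gamma_from_moments(21.7, 4)),
    # post-ICU course (monthly cycles)
    param("p_ward_discharge", "probability", 0.85, 0.70, 0.95,
          dist = beta_from_moments(0.85, 0.05)),
    param("p_ward_death", "probability", 0.02, 0.01, 0.04,
          dist = beta_from_moments(0.02, 0.005)),
    param("p_death_discharged", "probability", 0.0028, 0.0020, 0.0050,
          dist = beta_from_moments(0.0028, 0.0006)),
    # utilities
    param("u_ward", "utility", 0.55, 0.45, 0.65,
          dist = beta_from_moments(0.55, 0.05)),
    param("u_discharged", "utility", 0.75, 0.65, 0.85,
          dist = beta_from_moments(0.75, 0.05))
  )
}

#' Named scenarios for the CRBSI case
#'
#' `null_intervention` removes every difference between the arms: early
#' detection gets the late-detection mortality and length-of-stay effects
#' and the technology price is zero.
#'
#' @return Named list of override lists for [scenario()].
#' @export
crbsi_scenarios <- function() {
  base <- base_values(crbsi_parameter_set())
  list(
    null_intervention = list(
      p_death_icu_early = base[["p_death_icu_late"]],
      los_extra_early = base[["los_extra_late"]],
      price_per_bed = 0
    )
  )
}

crbsi_markov <- function(v) {
  p <- matrix(0, 4, 4)
  # icu row exists for completeness; post-tree entry never occupies it
  p[1, 2] <- 0.95; p[1, 4] <- 0.05
  p[2, 3] <- v[["p_ward_discharge"]]
  p[2, 4] <- v[["p_ward_death"]]
  p[2, 2] <- 1 - v[["p_ward_discharge"]] - v[["p_ward_death"]]
  p[3, 4] <- v[["p_death_discharged"]]
  p[3, 3] <- 1 - v[["p_death_discharged"]]
  p[4, 4] <- 1
  state_model(
    states = list(
      health_state("icu", utility = 0.30),
      health_state("ward", cost_per_cycle = v[["c_ward_cycle"]],
                   utility = v[["u_ward"]]),
      health_state("discharged", utility = v[["u_discharged"]]),
      health_state("dead", absorbing = TRUE)
    ),
    transitions = p, cycle_length = 1 / 12
  )
}

crbsi_tree <- function(v, timing = c("late", "early")) {
  timing <- match.arg(timing)
  p_die <- v[[paste0("p_death_icu_", timing)]]
  los_extra <- v[[paste0("los_extra_", timing)]]
  terminal <- function(p_dead) {
    c(icu = 0, ward = 1 - p_dead, discharged = 0, dead = p_dead)
  }
  decision_node("crbsi_occurrence", list(
    tree_branch(v[["p_crbsi"]],
                cost = (v[["los_icu_base"]] + los_extra) * v[["c_icu_day"]] +
                  v[["c_antibiotics"]],
                child = terminal(p_die)),
    tree_branch(1 - v[["p_crbsi"]],
                cost = v[["los_icu_base"]] * v[["c_icu_day"]],
                child = terminal(v[["p_death_icu_nocrbsi"]]))
  ))
}

#' Evaluate the ICU CRBSI early-detection case model
#'
#' A decision tree on infection occurrence and detection timing feeds a
#' four-state Markov model (ICU, post-ICU ward, discharged alive, dead; a
#' reconstruction — the published structure figure is not in the main
#' text). The tree carries the acute-episode payoffs: ICU days (baseline
#' plus an infection-attributable extra stay that early detection shortens)
#' at a per-day cost, antibiotics, and ICU death. Survivors enter the ward
#' state of the Markov model, which carries the remaining lifetime in
#' monthly cycles. The intervention arm detects all infections early and
#' additionally pays the technology price per bed divided by annual bed
#' throughput; the comparator detects late. Direct medical costs only.
#'
#' @param values Named parameter vector (see [crbsi_parameter_set()]).
#' @inheritParams build_cll_model
#' @return A `comparison_result` (comparator = late detection,
#'   intervention = early detection with analytics).
#' @examples
#' \donttest{
#' res <- build_crbsi_model(base_values(crbsi_parameter_set()))
#' -res$delta_cost  # per-patient savings at zero technology price
#' }
#' @export
build_crbsi_model <- function(values, horizon_years = 40, discount = 0.03,
                              half_cycle_correction = TRUE) {
  required <- crbsi_parameter_set()$name
  missing <- setdiff(required, names(values))
  if (length(missing)) {
    stop("missing parameter binding(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  plan <- cycle_plan(horizon_years, 1 / 12, discount, discount,
                     half_cycle_correction)
  markov <- crbsi_markov(values)

  eval_arm <- function(timing, tech_cost) {
    rb <- rollback_tree(crbsi_tree(values, timing))
    trace <- run_cohort(markov, rb$entry, plan)
    accumulate_outcomes(trace, markov, plan,
                        upfront_cost = rb$upfront_cost + tech_cost)
  }

  comparator <- eval_arm("late", tech_cost = 0)
  intervention <- eval_arm(
    "early",
    tech_cost = values[["price_per_bed"]] / values[["patients_per_bed"]]
  )
  compare_arms(comparator, intervention)
}
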