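#' Generate a synthetic parameter set
#'
#' Draws a parameter table with the statistical structure typical of an
#' early-evaluation input table: beta-distributed probabilities and
#' utilities, gamma-distributed costs and lognormal hazard ratios, each
#' with a base value, a containing low/high range and a matching
#' [dist_spec()]. Deterministic under `seed`.
#'
#' @param n_probability,n_utility,n_cost,n_hazard_ratio Number of
#'   parameters of each kind.
#' @param seed Integer seed.
#' @return A [parameter_set()].
#' @export
generate_parameter_set <- function(n_probability = 5, n_utility = 3,
                                   n_cost = 4, n_hazard_ratio = 1, seed = 1) {
  stopifnot(n_probability >= 0, n_utility >= 0, n_cost >= 0, n_hazard_ratio >= 0)
  set.seed(seed)
  rows <- list()

  bounded_row <- function(name, kind, base) {
    lo <- max(base * 0.5, 1e-4)
    hi <- min(base * 1.5, 0.999)
    sd <- min((hi - lo) / 4, 0.9 * sqrt(base * (1 - base)))
    param(name, kind, base, lo, hi, dist = beta_from_moments(base, sd))
  }
  for (i in seq_len(n_probability)) {
    rows <- c(rows, list(bounded_row(paste0("p_", i), "probability",
                                     stats::runif(1, 0.01, 0.5))))
  }
  for (i in seq_len(n_utility)) {
    rows <- c(rows, list(bounded_row(paste0("u_", i), "utility",
                                     stats::runif(1, 0.4, 0.9))))
  }
  for (i in seq_len(n_cost)) {
    base <- stats::rlnorm(1, log(1000), 1)
    rows <- c(rows, list(param(paste0("c_", i), "cost", base,
                               base * 0.5, base * 1.5,
                               dist = gamma_from_moments(base, base * 0.25))))
  }
  for (i in seq_len(n_hazard_ratio)) {
    base <- stats::rlnorm(1, log(0.7), 0.25)
    rows <- c(rows, list(param(paste0("hr_", i), "hazard_ratio", base,
                               base * 0.5, base * 1.8,
                               dist = lognormal_from_interval(base, base * 0.5,
                                                              base * 1.8))))
  }
  do.call(parameter_set, rows)
}

#' Generate a synthetic EHR-like patient table
#'
#' Emulates the patient-level tables a data-feasibility audit consumes:
#' enrolment dates over a recruitment window, exponential follow-up with
#' administrative censoring, site labels, demographics and a binary
#' outcome. Each field is then masked to missing independently
#' (missing-completely-at-random) at its configured rate. Deterministic
#' under `seed`.
#'
#' @param n_patients Number of rows (>= 1).
#' @param enrolment_start First enrolment date (`Date` or string).
#' @param enrolment_years Length of the recruitment window in years.
#' @param follow_up_mean_years Mean of the exponential follow-up time.
#' @param admin_censor_years Administrative censoring after enrolment.
#' @param missingness Named vector of per-field missingness rates in
#'   \[0, 1\] (names must be generated columns; `patient_id` cannot be
#'   masked).
#' @param n_sites Number of sites labels are drawn from.
#' @param seed Integer seed.
#' @return Data frame with columns `patient_id`, `site`, `enrolment_date`,
#'   `last_contact_date`, `age`, `sex`, `outcome`.
#' @export
generate_patient_table <- function(n_patients = 100,
                                   enrolment_start = "2015-01-01",
                                   enrolment_years = 2,
                                   follow_up_mean_years = 3,
                                   admin_censor_years = 5,
                                   missingness = c(),
                                   n_sites = 1,
                                   seed = 1) {
  stopifnot(n_patients >= 1, n_sites >= 1, follow_up_mean_years > 0)
  if (length(missingness)) {
    stopifnot(!is.null(names(missingness)), all(missingness >= 0),
              all(missingness <= 1))
  }
  set.seed(seed)
  start <- as.Date(enrolment_start)
  enrol <- start + round(stats::runif(n_patients, 0, enrolment_years * 365.25))
  fu <- pmin(stats::rexp(n_patients, rate = 1 / follow_up_mean_years),
             admin_censor_years)
  df <- data.frame(
    patient_id = sprintf("pt%05d", seq_len(n_patients)),
    site = paste0("site_", sample.int(n_sites, n_patients, replace = TRUE)),
    enrolment_date = enrol,
    last_contact_date = enrol + round(fu * 365.25),
    age = round(stats::rnorm(n_patients, 65, 10)),
    sex = sample(c("F", "M"), n_patients, replace = TRUE),
    outcome = stats::rbinom(n_patients, 1, 0.3),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(names(missingness), setdiff(names(df), "patient_id"))
  if (length(bad)) stop("missingness configured for unknown field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (f in names(missingness)) {
    mask <- stats::runif(n_patients) < missingness[[f]]
    df[[f]][mask] <- NA
  }
  df
}
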