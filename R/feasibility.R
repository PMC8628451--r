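#' Define a quantitative data requirement
#'
#' Requirements gate whether a candidate development dataset is fit for
#' building analytics: minimum sample size, minimum median follow-up,
#' maximum missingness per field, and so on. The package computes metrics
#' and applies comparisons; thresholds always come from the user — they
#' encode clinical judgement, not package defaults.
#'
#' @param metric One of `"sample_size"`, `"median_follow_up"`,
#'   `"missingness_fraction"`, `"site_count"`,
#'   `"outcome_capture_fraction"`.
#' @param comparator `">="` or `"<="`.
#' @param threshold Numeric threshold (fractions must lie in \[0, 1\]).
#' @param field Column name the metric applies to (required for
#'   `missingness_fraction`).
#' @param rationale Free-text justification, echoed in reports.
#' @return One-row data frame; combine with `rbind()`.
#' @export
data_requirement <- function(metric, comparator, threshold, field = NA_character_,
                             rationale = "") {
  metric <- match.arg(metric, c("sample_size", "median_follow_up",
                                "missingness_fraction", "site_count",
                                "outcome_capture_fraction"))
  comparator <- match.arg(comparator, c(">=", "<="))
  stopifnot(is.finite(threshold))
  if (metric %in% c("missingness_fraction", "outcome_capture_fraction") &&
      (threshold < 0 || threshold > 1)) {
    stop("threshold for ", metric, " must lie in [0, 1]", call. = FALSE)
  }
  if (metric == "missingness_fraction" && is.na(field)) {
    stop("missingness_fraction requires a field name", call. = FALSE)
  }
  data.frame(metric = metric, field = field, comparator = comparator,
             threshold = threshold, rationale = rationale,
             stringsAsFactors = FALSE)
}

parse_date_col <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  for (fmt in c("%Y-%m-%d", "%Y/%m/%d", "%d-%m-%Y", "%d/%m/%Y")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.Date(x[miss], format = fmt)
  }
  out
}

#' Audit a patient-level dataset against data requirements
#'
#' Computes the quantitative fitness metrics of a candidate development
#' dataset — sample size, median follow-up (last contact minus enrolment,
#' in years, over patients with both dates; patients with unparseable or
#' missing dates are counted in a separate "follow-up unknown" fraction
#' rather than silently dropped), per-field missingness, site count and
#' outcome capture — and checks each supplied requirement. The overall
#' verdict is `"not-feasible"` iff at least one requirement fails.
#'
#' @param records Patient-level data frame.
#' @param spec Column-role mapping: a list with `enrolment` and
#'   `last_contact` (date column names) and optionally `site`, `outcome`
#'   and `fields` (columns to report missingness for; defaults to all).
#' @param requirements Data frame of [data_requirement()] rows (may be
#'   empty: metrics are still reported, the verdict is then feasible).
#' @return A `data_audit_report`: `metrics` (named list), `missingness`
#'   (named vector), `requirements` (with `observed` and `verdict`
#'   columns), `overall_verdict`, `narrative` (character lines).
#' @export
audit_dataset <- function(records, spec, requirements = NULL) {
  stopifnot(is.data.frame(records), is.list(spec))
  for (role in c("enrolment", "last_contact")) {
    if (is.null(spec[[role]]) || !spec[[role]] %in% names(records)) {
      stop("spec role '", role, "' missing or not a column of records",
           call. = FALSE)
    }
  }
  fields <- spec$fields %||% names(records)
  unknown <- setdiff(fields, names(records))
  if (length(unknown)) stop("spec fields not in records: ",
                            paste(unknown, collapse = ", "), call. = FALSE)

  enrol <- parse_date_col(records[[spec$enrolment]])
  last <- parse_date_col(records[[spec$last_contact]])
  fu_years <- as.numeric(last - enrol) / 365.25
  fu_known <- !is.na(fu_years)

  missingness <- vapply(fields, function(f) mean(is.na(records[[f]])), numeric(1))
  metrics <- list(
    sample_size = nrow(records),
    median_follow_up = if (any(fu_known)) stats::median(fu_years[fu_known]) else NA_real_,
    follow_up_unknown_fraction = mean(!fu_known),
    site_count = if (!is.null(spec$site) && spec$site %in% names(records))
      length(unique(records[[spec$site]][!is.na(records[[spec$site]])])) else NA_integer_,
    outcome_capture_fraction = if (!is.null(spec$outcome) && spec$outcome %in% names(records))
      1 - mean(is.na(records[[spec$outcome]])) else NA_real_
  )

  reqs <- requirements
  if (is.null(reqs)) reqs <- data_requirement("sample_size", ">=", 0)[0, ]
  observed <- vapply(seq_len(nrow(reqs)), function(i) {
    m <- reqs$metric[i]
    if (m == "missingness_fraction") {
      f <- reqs$field[i]
      if (!f %in% names(missingness)) {
        stop("requirement on missingness of unknown field '", f, "'", call. = FALSE)
      }
      missingness[[f]]
    } else {
      as.numeric(metrics[[m]])
    }
  }, numeric(1))
  verdict <- vapply(seq_len(nrow(reqs)), function(i) {
    obs <- observed[i]
    if (is.na(obs)) return("fail")
    ok <- if (reqs$comparator[i] == ">=") obs >= reqs$threshold[i]
          else obs <= reqs$threshold[i]
    if (ok) "pass" else "fail"
  }, character(1))
  reqs$observed <- observed
  reqs$verdict <- verdict
  overall <- if (any(verdict == "fail")) "not-feasible" else "feasible"

  narrative <- c(
    sprintf("Sample size: %d patients across %s site(s).", metrics$sample_size,
            ifelse(is.na(metrics$site_count), "unreported", metrics$site_count)),
    sprintf("Median follow-up: %s years (%.1f%% of patients with unknown follow-up).",
            ifelse(is.na(metrics$median_follow_up), "unknown",
                   sprintf("%.2f", metrics$median_follow_up)),
            100 * metrics$follow_up_unknown_fraction),
    sprintf("Field missingness ranges from %.1f%% to %.1f%%.",
            100 * min(missingness), 100 * max(missingness)),
    if (nrow(reqs)) sprintf("%d of %d requirements met; verdict: %s.",
                            sum(verdict == "pass"), nrow(reqs), overall)
    else "No requirements supplied; metrics reported descriptively.",
    "Selection bias and representativeness: not assessed."
  )

  structure(list(metrics = metrics, missingness = missingness,
                 requirements = reqs, overall_verdict = overall,
                 narrative = narrative),
            class = "data_audit_report")
}

#' @export
print.data_audit_report <- function(x, ...) {
  cat(x$narrative, sep = "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a PICO scope ledger
#'
#' Captures the scope of a planned evaluation — Population, Intervention,
#' Comparator, Outcomes — together with the barriers to successful
#' development and implementation, each graded surmountable or
#' insurmountable.
#'
#' @param population,intervention,comparator,outcomes Non-empty scope text.
#' @param barriers List of [barrier()] entries.
#' @return A `scope_ledger`.
#' @export
scope_ledger <- function(population, intervention, comparator, outcomes,
                         barriers = list()) {
  structure(list(population = population, intervention = intervention,
                 comparator = comparator, outcomes = outcomes,
                 barriers = barriers),
            class = "scope_ledger")
}

#' @rdname scope_ledger
#' @param description Barrier description.
#' @param severity `"surmountable"` or `"insurmountable"`.
#' @export
barrier <- function(description, severity = c("surmountable", "insurmountable")) {
  severity <- match.arg(severity)
  structure(list(description = description, severity = severity),
            class = "barrier")
}

#' Issue a go/no-go verdict on a scope ledger
#'
#' Development proceeds to economic evaluation iff the ledger records no
#' insurmountable barrier; otherwise the verdict is to re-scope (or cease,
#' per `on_block`) and the blocking barriers are listed.
#'
#' @param ledger A [scope_ledger()]; all four PICO fields must be non-empty.
#' @param on_block Verdict when an insurmountable barrier exists.
#' @return List with `verdict` (`"proceed-to-evaluation"`, `"re-scope"` or
#'   `"cease"`), `blocking` (descriptions of insurmountable barriers) and
#'   `surmountable` (the rest, candidates for scenario analyses).
#' @export
evaluate_scope <- function(ledger, on_block = c("re-scope", "cease")) {
  stopifnot(inherits(ledger, "scope_ledger"))
  on_block <- match.arg(on_block)
  for (f in c("population", "intervention", "comparator", "outcomes")) {
    v <- ledger[[f]]
    if (!is.character(v) || length(v) == 0 || !any(nzchar(trimws(v)))) {
      stop("PICO field '", f, "' is empty", call. = FALSE)
    }
  }
  sev <- vapply(ledger$barriers, `[[`, character(1), "severity")
  desc <- vapply(ledger$barriers, `[[`, character(1), "description")
  blocking <- desc[sev == "insurmountable"]
  list(
    verdict = if (length(blocking)) on_block else "proceed-to-evaluation",
    blocking = blocking,
    surmountable = desc[sev == "surmountable"]
  )
}
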