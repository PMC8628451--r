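#' Read and write parameter sets as delimited tables
#'
#' Parameter sets round-trip through tab-separated files with the columns
#' `name, kind, base, low, high, dist_family, dist_arg1, dist_arg2,
#' dist_arg3, source_tag`. Reading re-validates every row (ranges, kind
#' supports, distribution arguments).
#'
#' @param params A [parameter_set()].
#' @param path File path.
#' @return `read_parameter_set` returns a validated [parameter_set()];
#'   `write_parameter_set` returns `path` invisibly.
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "parameter_set"))
  utils::write.table(as.data.frame(params), path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(name = "character", kind = "character",
                                         dist_family = "character",
                                         source_tag = "character"))
  needed <- c("name", "kind", "base", "low", "high", "dist_family",
              "dist_arg1", "dist_arg2", "dist_arg3", "source_tag")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("parameter file lacks column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    dist <- NULL
    if (!is.na(df$dist_family[i])) {
      args <- c(df$dist_arg1[i], df$dist_arg2[i], df$dist_arg3[i])
      dist <- do.call(dist_spec, c(list(df$dist_family[i]),
                                   as.list(args[!is.na(args)])))
    }
    param(df$name[i], df$kind[i], df$base[i], df$low[i], df$high[i],
          dist = dist, source_tag = df$source_tag[i])
  })
  do.call(parameter_set, rows)
}

#' Read a Markov model structure from a YAML config
#'
#' The config declares `cycle_length` (years), a `states` list (each with
#' `name` and optional `cost`, `utility`, `absorbing`) and `transitions`,
#' either as a dense row-major `matrix` (list of rows in state order) or as
#' an `edges` list of `{from, to, prob}` entries — any probability mass a
#' row leaves unassigned is the implicit "stay" probability on the
#' diagonal.
#'
#' @param path Path to the YAML file.
#' @return A [state_model()].
#' @export
read_state_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$states)) stop("config lacks a 'states' block", call. = FALSE)
  states <- lapply(cfg$states, function(s) {
    health_state(s$name,
                 cost_per_cycle = s$cost %||% 0,
                 utility = s$utility %||% 0,
                 absorbing = isTRUE(s$absorbing))
  })
  nm <- vapply(states, `[[`, character(1), "name")
  n <- length(nm)
  tr <- cfg$transitions
  if (!is.null(tr$matrix)) {
    m <- do.call(rbind, lapply(tr$matrix, as.numeric))
  } else if (!is.null(tr$edges)) {
    m <- matrix(0, n, n, dimnames = list(nm, nm))
    for (e in tr$edges) {
      if (!e$from %in% nm || !e$to %in% nm) {
        stop("edge references unknown state: ", e$from, " -> ", e$to,
             call. = FALSE)
      }
      m[e$from, e$to] <- e$prob
    }
    # unassigned mass stays put
    diag(m) <- diag(m) + pmax(0, 1 - rowSums(m))
  } else {
    stop("config 'transitions' needs either 'matrix' or 'edges'", call. = FALSE)
  }
  state_model(states, m, cycle_length = as.numeric(cfg$cycle_length %||% (1 / 12)))
}

#' Tabulate a comparison result
#'
#' Machine-readable mirror of the customary results-table layout: one row
#' per arm, an incremental row, and an ICER row, all unrounded.
#'
#' @param result A `comparison_result`.
#' @param arm_labels Length-2 labels for comparator and intervention.
#' @return Data frame with columns `row`, `cost`, `life_years`, `qalys`.
#' @export
comparison_table <- function(result,
                             arm_labels = c("comparator", "intervention")) {
  stopifnot(inherits(result, "comparison_result"), length(arm_labels) == 2L)
  data.frame(
    row = c(arm_labels, "incremental", "icer"),
    cost = c(result$comparator$total_cost, result$intervention$total_cost,
             result$delta_cost, NA_real_),
    life_years = c(result$comparator$life_years, result$intervention$life_years,
                   result$delta_ly, result$icer_per_ly),
    qalys = c(result$comparator$qalys, result$intervention$qalys,
              result$delta_qaly, result$icer_per_qaly),
    stringsAsFactors = FALSE
  )
}

#' Render a comparison result for reading
#'
#' Human-oriented rendering of [comparison_table()]: costs rounded to whole
#' currency units and effects to two decimals by default; undefined ICERs
#' are spelled out rather than printed as infinities.
#'
#' @inheritParams comparison_table
#' @param label Optional scenario label printed as a heading.
#' @param digits_cost,digits_effect Rounding for display.
#' @return Character vector of report lines (invisibly printed by
#'   `print.comparison_result`).
#' @export
render_comparison_report <- function(result, label = NULL,
                                     arm_labels = c("comparator", "intervention"),
                                     digits_cost = 0, digits_effect = 2) {
  tab <- comparison_table(result, arm_labels)
  fmt <- function(x, d) ifelse(is.na(x), "-", formatC(round(x, d), format = "f",
                                                      digits = d, big.mark = ","))
  lines <- c(
    if (!is.null(label)) paste0("== ", label, " =="),
    sprintf("%-22s %15s %12s %12s", "", "cost", "life years", "QALYs"))
  for (i in 1:3) {
    lines <- c(lines, sprintf("%-22s %15s %12s %12s", tab$row[i],
                              fmt(tab$cost[i], digits_cost),
                              fmt(tab$life_years[i], digits_effect),
                              fmt(tab$qalys[i], digits_effect)))
  }
  icer_txt <- function(x) if (is.na(x)) "undefined (no effect difference)"
                          else fmt(x, digits_cost)
  lines <- c(lines,
             sprintf("%-22s %15s %12s %12s", "ICER", "-",
                     icer_txt(result$icer_per_ly), icer_txt(result$icer_per_qaly)),
             paste0("dominance: ", result$dominance_label))
  lines
}
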