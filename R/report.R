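#' Render the full results report
#'
#' Deterministic plain-text report reproducing the layout of the published
#' results: the three-scenario cost-effectiveness table (euros rounded to
#' integers, complications to three decimals, dominated rows labelled
#' instead of an ICER) and the per-complication savings table, optionally
#' followed by a pricing summary. The renderer performs no arithmetic
#' beyond display rounding.
#'
#' @param scenario_table a [run_all_scenarios()] result.
#' @param savings named savings vector from [savings_by_complication()]
#'   (optional).
#' @param pricing list of `vcd_pricing` results (optional).
#' @return character vector of report lines.
#' @export
render_report <- function(scenario_table, savings = NULL, pricing = NULL) {
  lines <- c("Total and incremental effectiveness and costs",
             sprintf("%-16s %-10s %13s %12s %12s %12s %s",
                     "scenario", "strategy", "complications", "total EUR",
                     "prevented", "incr. EUR", "ICER"))
  for (i in seq_len(nrow(scenario_table))) {
    r <- scenario_table[i, ]
    icer_txt <- if (is.na(r$status)) {
      ""
    } else if (r$status == "tradeoff") {
      fmt_euro(r$icer)
    } else {
      # capitalized, as in the published table
      paste0(toupper(substring(r$status, 1, 1)), substring(r$status, 2))
    }
    lines <- c(lines, sprintf(
      "%-16s %-10s %13s %12s %12s %12s %s",
      r$scenario, r$strategy, fmt_compl(r$expected_complications),
      fmt_euro(r$total_cost),
      if (is.na(r$delta_prevented)) "" else fmt_compl(r$delta_prevented),
      if (is.na(r$delta_cost)) "" else fmt_euro(r$delta_cost), icer_txt))
  }
  if (!is.null(savings)) {
    lines <- c(lines, "", "Cost savings by complication (100 % averted)",
               vapply(complications(), function(c_id)
                 sprintf("%-24s %6s", c_id, fmt_euro(savings[[c_id]])),
                 character(1)))
  }
  if (!is.null(pricing)) {
    lines <- c(lines, "", "Value-based pricing",
               vapply(pricing, function(p)
                 sprintf("%-24s %6s", p$method, fmt_euro(p$premium)),
                 character(1)))
  }
  lines
}

#' Write the scenario results table as CSV
#'
#' @param scenario_table a [run_all_scenarios()] result.
#' @param path output CSV path.
#' @param rounded write display-rounded values (euros to integers,
#'   complications to 3 decimals) instead of full precision.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(scenario_table, path, rounded = FALSE) {
  out <- scenario_table
  if (rounded) {
    for (col in c("complication_cost", "total_cost", "delta_cost", "icer")) {
      out[[col]] <- round_euro(out[[col]])
    }
    for (col in c("expected_complications", "delta_prevented")) {
      out[[col]] <- round_compl(out[[col]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Every file-producing run can be accompanied by a manifest capturing the
#' command, its inputs and options, the package version and a timestamp —
#' enough to re-run the command.
#'
#' @param command command or subcommand name.
#' @param inputs character vector of input file paths or fixture ids.
#' @param options named list of options used.
#' @return a list of class `vcd_manifest`.
#' @export
run_manifest <- function(command, inputs = character(), options = list()) {
  structure(list(command = command, inputs = inputs, options = options,
                 tool_version = as.character(utils::packageVersion("vcdvalue")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "vcd_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Plot complication cost against reduction level
#'
#' Line plot of an [effectiveness_sweep()]: total complication cost (or
#' savings) per catheterization as device effectiveness improves. Requires
#' ggplot2.
#'
#' @param sweep an [effectiveness_sweep()] result.
#' @return a ggplot object.
#' @export
plot_sweep <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_ctx("plot_sweep requires the ggplot2 package")
  }
  ggplot2::ggplot(sweep, ggplot2::aes(x = reduction_level,
                                      y = complication_cost)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reduction level (fraction of targeted rates removed)",
                  y = "complication cost (EUR per catheterization)")
}

utils::globalVariables("complication_cost")
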