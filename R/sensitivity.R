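# Parameter paths address one probability inside a parameterization:
#   <strategy>.rates.<complication>
#   <strategy>.treatments.<complication>.<treatment_key>
#   <strategy>.failure_prob
# Setting a value also updates any copy of the strategy embedded as another
# strategy's fallback (the failure arm shares the comparator's parameters).

parse_target <- function(params, target) {
  parts <- strsplit(target, ".", fixed = TRUE)[[1]]
  s_name <- parts[1]
  if (!(s_name %in% names(params$strategies))) {
    stop_ctx("target '%s': unknown strategy '%s'", target, s_name)
  }
  if (length(parts) == 2L && parts[2] == "failure_prob") {
    return(list(strategy = s_name, kind = "failure_prob"))
  }
  if (length(parts) == 3L && parts[2] == "rates" &&
      parts[3] %in% complications()) {
    return(list(strategy = s_name, kind = "rate", complication = parts[3]))
  }
  if (length(parts) == 4L && parts[2] == "treatments" &&
      parts[3] %in% complications() && parts[4] %in% treatment_keys()) {
    return(list(strategy = s_name, kind = "treatment",
                complication = parts[3], treatment = parts[4]))
  }
  stop_ctx("cannot resolve target path '%s'", target)
}

spec_get <- function(spec, t) {
  switch(t$kind,
    failure_prob = spec$failure_prob,
    rate = spec$rates[[t$complication]],
    treatment = {
      rl <- spec$treatments[[t$complication]]
      i <- match(t$treatment, rl$treatment)
      if (is.na(i)) {
        stop_ctx("strategy '%s' has no '%s' rule for '%s'", spec$name,
                 t$treatment, t$complication)
      }
      rl$prob[i]
    })
}

spec_set <- function(spec, t, value) {
  switch(t$kind,
    failure_prob = spec$failure_prob <- value,
    rate = spec$rates[[t$complication]] <- value,
    treatment = {
      rl <- spec$treatments[[t$complication]]
      i <- match(t$treatment, rl$treatment)
      if (is.na(i)) {
        stop_ctx("strategy '%s' has no '%s' rule for '%s'", spec$name,
                 t$treatment, t$complication)
      }
      rl$prob[i] <- value
      spec$treatments[[t$complication]] <- rl
    })
  spec
}

#' Read one probability from a parameterization by target path
#'
#' @param params a [model_parameters()] object.
#' @param target path string, e.g. `"MC.rates.hematoma"`,
#'   `"VCD.treatments.hematoma.transfusion_pta"`, `"VCD.failure_prob"`.
#' @return the addressed probability (fraction).
#' @export
get_parameter <- function(params, target) {
  t <- parse_target(params, target)
  spec_get(params$strategies[[t$strategy]], t)
}

#' Substitute one probability in a parameterization by target path
#'
#' Returns a modified copy; the input is never mutated. The substitution
#' also propagates into any fallback copy of the addressed strategy (a
#' device's failure arm carries the comparator's rates and rules).
#'
#' @inheritParams get_parameter
#' @param value replacement probability (fraction in \[0, 1\]).
#' @return a new `vcd_params` object.
#' @export
set_parameter <- function(params, target, value) {
  if (!is_prob(value)) {
    stop_ctx("target '%s': replacement value %s is not a probability",
             target, paste(value, collapse = ","))
  }
  t <- parse_target(params, target)
  params$strategies[[t$strategy]] <-
    spec_set(params$strategies[[t$strategy]], t, value)
  if (t$kind != "failure_prob") {
    for (nm in names(params$strategies)) {
      fb <- params$strategies[[nm]]$fallback
      if (!is.null(fb) && identical(fb$name, t$strategy)) {
        params$strategies[[nm]]$fallback <- spec_set(fb, t, value)
      }
    }
  }
  params
}

#' Define an uncertainty range for one parameter
#'
#' @param target a parameter path (see [get_parameter()]).
#' @param low,high range bounds, fractions with `0 <= low <= high <= 1`.
#' @return one-row data frame with columns `target`, `low`, `high`.
#' @export
parameter_range <- function(target, low, high) {
  if (!(is_prob(low) && is_prob(high) && low <= high)) {
    stop_ctx("target '%s': need 0 <= low <= high <= 1 (got %s, %s)",
             target, low, high)
  }
  data.frame(target = target, low = low, high = high,
             stringsAsFactors = FALSE)
}

#' Read DSA parameter ranges from CSV
#'
#' Expects columns `target_path`, `low`, `high`. An illustrative synthetic
#' fixture (point estimates ±30 % relative, clamped to \[0, 1\]) ships at
#' `system.file("extdata", "dsa_ranges_illustrative_synthetic.csv",
#' package = "vcdvalue")`; it stands in for unavailable published
#' confidence limits and carries no evidential weight.
#'
#' @param path CSV file path.
#' @return data frame of ranges as produced by [parameter_range()].
#' @export
read_ranges_csv <- function(path) {
  if (!file.exists(path)) stop_ctx("ranges file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target_path", "low", "high")
  if (!all(need %in% names(df))) {
    stop_ctx("ranges CSV must have columns %s", paste(need, collapse = ", "))
  }
  do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    parameter_range(df$target_path[i], as.numeric(df$low[i]),
                    as.numeric(df$high[i]))))
}

dsa_outcome <- function(params, outcome, intervention, comparator) {
  sched <- schedule_for(params)
  res_i <- evaluate_strategy(params$strategies[[intervention]], sched)
  res_c <- evaluate_strategy(params$strategies[[comparator]], sched)
  inc <- incremental_analysis(res_i, res_c)
  switch(outcome,
    incremental_cost = list(value = inc$delta_cost, note = ""),
    incremental_prevented = list(value = inc$delta_prevented, note = ""),
    icer = if (inc$status == "tradeoff") {
      list(value = inc$icer, note = "")
    } else {
      list(value = NA_real_, note = inc$status)
    })
}

#' One-way deterministic sensitivity analysis
#'
#' Varies each effect parameter separately to the bounds of its range while
#' holding every other parameter at its point estimate (ceteris paribus),
#' and records the model outcome at both endpoints. The input
#' parameterization is never modified. With the `icer` outcome, endpoints
#' at which the intervention is dominated (or dominant/equivalent) have no
#' meaningful ICER; they are flagged in the `note` column instead of
#' computed.
#'
#' @param params a [model_parameters()] object (point estimates).
#' @param ranges data frame of ranges ([parameter_range()] /
#'   [read_ranges_csv()]); each range must contain its point estimate.
#' @param outcome `"incremental_cost"` (default), `"incremental_prevented"`,
#'   or `"icer"`.
#' @param intervention,comparator strategy names (defaults `"VCD"`, `"MC"`).
#' @return data frame with one row per range: `target`, `outcome_at_low`,
#'   `outcome_at_high`, `spread` (absolute difference), `note`.
#' @export
one_way_dsa <- function(params, ranges,
                        outcome = c("incremental_cost",
                                    "incremental_prevented", "icer"),
                        intervention = "VCD", comparator = "MC") {
  outcome <- match.arg(outcome)
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    target <- ranges$target[i]
    point <- get_parameter(params, target)
    if (point < ranges$low[i] - 1e-12 || point > ranges$high[i] + 1e-12) {
      stop_ctx("target '%s': point estimate %g outside range [%g, %g]",
               target, point, ranges$low[i], ranges$high[i])
    }
    at_low <- dsa_outcome(set_parameter(params, target, ranges$low[i]),
                          outcome, intervention, comparator)
    at_high <- dsa_outcome(set_parameter(params, target, ranges$high[i]),
                           outcome, intervention, comparator)
    data.frame(target = target,
               outcome_at_low = at_low$value,
               outcome_at_high = at_high$value,
               spread = abs(at_high$value - at_low$value),
               note = paste(unique(c(at_low$note, at_high$note)[
                 nzchar(c(at_low$note, at_high$note))]), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tornado ordering of sensitivity results
#'
#' Sorts DSA rows by spread, largest first — the order in which bars appear
#' in a tornado chart. Ties are broken by target path, lexicographically
#' (stable and deterministic).
#'
#' @param rows a [one_way_dsa()] result.
#' @return the same data frame, reordered.
#' @export
tornado_order <- function(rows) {
  spread <- ifelse(is.na(rows$spread), -Inf, rows$spread)
  rows[order(-spread, rows$target), , drop = FALSE]
}

#' Tornado chart of one-way sensitivity results
#'
#' Horizontal-bar rendering of [tornado_order()] output. Requires ggplot2.
#'
#' @param rows a [one_way_dsa()] result.
#' @param base_value outcome at the point estimates (bar origin); computed
#'   positions are `outcome_at_low` and `outcome_at_high`.
#' @return a ggplot object.
#' @export
plot_tornado <- function(rows, base_value) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_ctx("plot_tornado requires the ggplot2 package")
  }
  ord <- tornado_order(rows)
  ord$target <- factor(ord$target, levels = rev(ord$target))
  ggplot2::ggplot(ord) +
    ggplot2::geom_segment(ggplot2::aes(
      x = outcome_at_low, xend = outcome_at_high,
      y = target, yend = target), linewidth = 4) +
    ggplot2::geom_vline(xintercept = base_value, linetype = "dashed") +
    ggplot2::labs(x = "outcome (EUR per catheterization)", y = NULL)
}

utils::globalVariables(c("outcome_at_low", "outcome_at_high", "target",
                         "reduction_level", "savings_vs_reference"))
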