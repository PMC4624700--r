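#' Expected complications per catheterization
#'
#' Complications are modeled as independent events, and effectiveness counts
#' every complication (a patient can contribute several), so the expected
#' number per catheterization is the sum of the six marginal probabilities.
#'
#' @param rates named numeric vector of complication probabilities
#'   (fractions), names = [complications()].
#' @return expected complications per catheterization (in \[0, 6\]).
#' @export
expected_complications <- function(rates) {
  missing <- setdiff(complications(), names(rates))
  if (length(missing) > 0L) {
    stop_ctx("rates missing complication(s): %s",
             paste(missing, collapse = ", "))
  }
  sum(rates[complications()])
}

#' Expected complication-attributable cost of one branch
#'
#' Probability-weighted treatment cost summed over complications:
#' \deqn{\sum_c r_c \sum_{t \in rules(c)} p_t \cdot cost(t)}
#' Treatments within a complication are independent, so their expected
#' costs add (retroperitoneal hemorrhage carries both a transfusion and an
#' endovascular/surgery rule). Untreated complications (probability-zero
#' rules) contribute no cost but still count towards effectiveness.
#'
#' @param rates named complication probabilities (fractions).
#' @param rules named list of treatment rules as in [strategy_spec()].
#' @param schedule a [build_cost_schedule()] result.
#' @return expected complication-attributable cost (EUR per
#'   catheterization).
#' @export
expected_complication_cost <- function(rates, rules, schedule) {
  total <- 0
  for (c_id in complications()) {
    r <- rates[[c_id]]
    if (is.null(r)) stop_ctx("rates missing complication '%s'", c_id)
    rl <- rules[[c_id]]
    if (is.null(rl) || nrow(rl) == 0L) next
    unknown <- setdiff(rl$treatment, names(schedule$treatment_cost))
    if (length(unknown) > 0L) {
      stop_ctx("unknown treatment key(s) for '%s': %s", c_id,
               paste(unknown, collapse = ", "))
    }
    total <- total + r * sum(rl$prob * schedule$treatment_cost[rl$treatment])
  }
  total
}

#' Evaluate a strategy on a cost schedule
#'
#' Expected outcomes of one hemostasis strategy per catheterization. With a
#' failure arm (probability `f = failure_prob`) both effectiveness and cost
#' are the two-branch mixture
#' \deqn{(1-f)\,E_{device} + f\,E_{fallback}}
#' and the total cost adds the base catheterization cost (identical across
#' strategies, since hemostasis itself is covered by the base DRG).
#'
#' @param spec a [strategy_spec()].
#' @param schedule a [build_cost_schedule()] result.
#' @return an object of class `vcd_strategy_result` with fields
#'   `strategy_name`, `expected_complications`, `complication_cost`,
#'   `total_cost` (all full precision).
#' @export
evaluate_strategy <- function(spec, schedule) {
  f <- spec$failure_prob
  if (f > 0 && is.null(spec$fallback)) {
    stop_ctx("strategy '%s' has failure_prob %g but no fallback",
             spec$name, f)
  }
  e_dev <- expected_complications(spec$rates)
  c_dev <- expected_complication_cost(spec$rates, spec$treatments, schedule)
  if (f > 0) {
    fb <- spec$fallback
    e_fb <- expected_complications(fb$rates)
    c_fb <- expected_complication_cost(fb$rates, fb$treatments, schedule)
    e <- (1 - f) * e_dev + f * e_fb
    cc <- (1 - f) * c_dev + f * c_fb
  } else {
    e <- e_dev
    cc <- c_dev
  }
  structure(list(strategy_name = spec$name,
                 expected_complications = e,
                 complication_cost = cc,
                 total_cost = schedule$base_cath_cost + cc),
            class = "vcd_strategy_result")
}

#' @export
print.vcd_strategy_result <- function(x, ...) {
  cat(sprintf("<vcd_strategy_result> %s: %s complications, total EUR %s (EUR %s complication-attributable)\n",
              x$strategy_name, fmt_compl(x$expected_complications),
              fmt_euro(x$total_cost), fmt_euro(x$complication_cost)))
  invisible(x)
}

#' Incremental analysis of two strategies
#'
#' Cost and effectiveness differences of an intervention against a
#' comparator evaluated on the same schedule, with dominance
#' classification. The sign convention follows the published tables:
#' `delta_prevented = comparator − intervention` expected complications, so
#' positive values mean the intervention prevents complications, and a
#' positive ICER is the price paid per complication prevented.
#'
#' Status is `"dominant"` (cheaper and more effective), `"dominated"` (more
#' expensive and less effective — no meaningful ICER), `"equivalent"` (both
#' deltas zero within `tol`), or `"tradeoff"` otherwise, in which case
#' `icer = delta_cost / delta_prevented` at full precision.
#'
#' @param intervention,comparator [evaluate_strategy()] results.
#' @param tol tie tolerance for classification (default `1e-12`; the model
#'   is pure floating-point arithmetic on fixed inputs).
#' @return an object of class `vcd_incremental` with fields `delta_cost`,
#'   `delta_prevented`, `status`, `icer` (NA unless status is tradeoff).
#' @export
incremental_analysis <- function(intervention, comparator, tol = 1e-12) {
  dc <- intervention$total_cost - comparator$total_cost
  dp <- comparator$expected_complications - intervention$expected_complications
  cost_zero <- abs(dc) <= tol
  prev_zero <- abs(dp) <= tol
  status <- if (cost_zero && prev_zero) {
    "equivalent"
  } else if (dc < -tol && dp > tol) {
    "dominant"
  } else if (dc > tol && dp < -tol) {
    "dominated"
  } else {
    "tradeoff"
  }
  structure(list(delta_cost = dc, delta_prevented = dp, status = status,
                 icer = if (status == "tradeoff") dc / dp else NA_real_),
            class = "vcd_incremental")
}

#' @export
print.vcd_incremental <- function(x, ...) {
  cat(sprintf("<vcd_incremental> delta cost EUR %s, prevented %s, %s%s\n",
              fmt_euro(x$delta_cost), fmt_compl(x$delta_prevented), x$status,
              if (x$status == "tradeoff")
                sprintf(", ICER EUR %s per averted complication",
                        fmt_euro(x$icer)) else ""))
  invisible(x)
}
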