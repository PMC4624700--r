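#' Construct a hypothetical device variant
#'
#' Scales selected device-branch complication rates by factors in \[0, 1\]
#' (0 = complication fully prevented, 1 = unchanged). The failure arm —
#' probability and fallback rates/rules — and the treatment rules are left
#' untouched: the hypothetical device changes what the device prevents, not
#' what happens when it fails.
#'
#' @param base a [strategy_spec()] with a device branch.
#' @param multipliers named numeric vector of factors in \[0, 1\], names
#'   from [complications()]; unnamed complications default to 1.
#' @return a new `vcd_strategy`.
#' @export
#' @examples
#' vcd <- paper_fixture("combined")$strategies$VCD
#' bleed_free <- make_hypothetical(vcd, c(hematoma = 0, rph = 0))
make_hypothetical <- function(base, multipliers) {
  unknown <- setdiff(names(multipliers), complications())
  if (length(unknown) > 0L) {
    stop_ctx("unknown complication(s) in multipliers: %s",
             paste(unknown, collapse = ", "))
  }
  if (any(multipliers < 0 | multipliers > 1)) {
    stop_ctx("reduction factors must lie in [0, 1]")
  }
  full <- stats::setNames(rep(1, length(complications())), complications())
  full[names(multipliers)] <- multipliers
  strategy_spec(base$name, base$rates * full[names(base$rates)],
                base$treatments, failure_prob = base$failure_prob,
                fallback = base$fallback)
}

#' Cost savings by fully averted complication
#'
#' For each complication: the strategy's complication-attributable cost
#' minus the same cost after setting that complication's device-branch rate
#' to zero (failure branch untouched) — the payer savings a device variant
#' preventing all occurrences of that complication would realize.
#'
#' @param device a [strategy_spec()] (typically the VCD strategy).
#' @param schedule a [build_cost_schedule()] result.
#' @return named numeric vector (EUR per catheterization), one entry per
#'   complication, full precision.
#' @export
savings_by_complication <- function(device, schedule) {
  ref <- evaluate_strategy(device, schedule)$complication_cost
  vapply(complications(), function(c_id) {
    zeroed <- make_hypothetical(device, stats::setNames(0, c_id))
    ref - evaluate_strategy(zeroed, schedule)$complication_cost
  }, numeric(1))
}

#' Effectiveness sweep over a set of complications
#'
#' Scales the device-branch rates of the target complications jointly from
#' unchanged (level 0) to fully prevented (level 1) in steps of `step`,
#' recording at each level the per-complication contributions to the mixed
#' complication cost, the total complication cost, and the savings against
#' the unreduced strategy. Because the model is linear in every rate, the
#' savings are exactly linear in the reduction level.
#'
#' @param device a [strategy_spec()].
#' @param targets character vector of complications to reduce (default the
#'   bleeding events, hematoma and retroperitoneal hemorrhage).
#' @param step reduction step as a fraction in (0, 1\] (default 0.1).
#' @param schedule a [build_cost_schedule()] result.
#' @return data frame with one row per reduction level: `reduction_level`,
#'   one column per complication (its contribution to the mixed
#'   complication cost, EUR), `complication_cost`, `savings_vs_reference`.
#' @export
effectiveness_sweep <- function(device, targets = c("hematoma", "rph"),
                                step = 0.1, schedule) {
  if (!(step > 0 && step <= 1)) stop_ctx("step must lie in (0, 1]")
  unknown <- setdiff(targets, complications())
  if (length(unknown) > 0L) {
    stop_ctx("unknown complication(s): %s", paste(unknown, collapse = ", "))
  }
  levels <- unique(c(seq(0, 1, by = step), 1))
  f <- device$failure_prob
  contribution <- function(spec) {
    per_branch <- function(rates, rules) {
      vapply(complications(), function(c_id) {
        rl <- rules[[c_id]]
        if (is.null(rl) || nrow(rl) == 0L) return(0)
        rates[[c_id]] * sum(rl$prob * schedule$treatment_cost[rl$treatment])
      }, numeric(1))
    }
    dev <- per_branch(spec$rates, spec$treatments)
    if (f > 0) {
      fb <- per_branch(spec$fallback$rates, spec$fallback$treatments)
      (1 - f) * dev + f * fb
    } else {
      dev
    }
  }
  ref_cost <- sum(contribution(device))
  rows <- lapply(levels, function(lv) {
    reduced <- make_hypothetical(
      device, stats::setNames(rep(1 - lv, length(targets)), targets))
    contrib <- contribution(reduced)
    cbind(data.frame(reduction_level = lv),
          as.data.frame(as.list(contrib)),
          data.frame(complication_cost = sum(contrib),
                     savings_vs_reference = ref_cost - sum(contrib)))
  })
  do.call(rbind, rows)
}

#' Full three-scenario results table
#'
#' Evaluates intervention and comparator in each scenario (combined,
#' diagnostic, interventional) and attaches the incremental analysis — the
#' published results table as a data frame. Values are full precision;
#' display rounding (euros to integers, complications to three decimals)
#' happens in [render_report()].
#'
#' @param fixture_source function mapping a scenario id to a
#'   [model_parameters()] object (default [paper_fixture]).
#' @param intervention,comparator strategy names within each
#'   parameterization (defaults `"VCD"` and `"MC"`).
#' @return data frame with one row per scenario and strategy, columns
#'   `scenario`, `strategy`, `expected_complications`, `complication_cost`,
#'   `total_cost`, and (on the intervention row) `delta_prevented`,
#'   `delta_cost`, `icer`, `status`.
#' @export
run_all_scenarios <- function(fixture_source = paper_fixture,
                              intervention = "VCD", comparator = "MC") {
  rows <- lapply(c("combined", "diagnostic", "interventional"), function(sc) {
    params <- fixture_source(sc)
    sched <- schedule_for(params)
    res_c <- evaluate_strategy(params$strategies[[comparator]], sched)
    res_i <- evaluate_strategy(params$strategies[[intervention]], sched)
    inc <- incremental_analysis(res_i, res_c)
    data.frame(
      scenario = sc,
      strategy = c(comparator, intervention),
      expected_complications = c(res_c$expected_complications,
                                 res_i$expected_complications),
      complication_cost = c(res_c$complication_cost, res_i$complication_cost),
      total_cost = c(res_c$total_cost, res_i$total_cost),
      delta_prevented = c(NA_real_, inc$delta_prevented),
      delta_cost = c(NA_real_, inc$delta_cost),
      icer = c(NA_real_, inc$icer),
      status = c(NA_character_, inc$status),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
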