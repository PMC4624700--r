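#' DRG difference cost
#'
#' Complications whose treatment is reimbursed through a higher-weighted
#' catheterization DRG (rather than a distinct DRG) are costed as the
#' difference between the higher- and lower-weighted DRG of the same
#' catheterization.
#'
#' @param higher reimbursement of the higher-weighted DRG (EUR).
#' @param lower reimbursement of the lower-weighted DRG (EUR).
#' @return `higher - lower` (EUR).
#' @export
#' @examples
#' drg_difference(6385.32, 1085.33)  # 5299.99
drg_difference <- function(higher, lower) {
  if (any(lower < 0)) stop_ctx("DRG reimbursements must be >= 0")
  if (any(higher < lower)) {
    stop_ctx("higher-weighted DRG (%s) below lower-weighted DRG (%s)",
             paste(higher, collapse = ","), paste(lower, collapse = ","))
  }
  higher - lower
}

#' Weighted diagnostic/interventional blend
#'
#' Costs for the combined diagnostic & interventional scenario are the
#' weighted average of the two subgroup values, default weights 1:2 (the
#' case mix of the underlying meta-analysis).
#'
#' @param diag diagnostic-scenario value (EUR).
#' @param interv interventional-scenario value (EUR).
#' @param w_diag,w_interv positive weights.
#' @return `(w_diag * diag + w_interv * interv) / (w_diag + w_interv)`.
#' @export
#' @examples
#' combined_value(5299.99, 2633.40)  # 3522.26
combined_value <- function(diag, interv, w_diag = 1, w_interv = 2) {
  if (w_diag <= 0 || w_interv <= 0) stop_ctx("weights must be > 0")
  (w_diag * diag + w_interv * interv) / (w_diag + w_interv)
}

.schedule_codes <- c("F49G", "F49A", "F24B", "F24A", "F19C", "F19A",
                     "F08E", "T61B")

#' Build the per-scenario cost schedule from a DRG table
#'
#' Translates DRG reimbursements into a base catheterization cost and one
#' euro cost per treatment key:
#' \describe{
#'   \item{diagnostic}{base = F49G; `transfusion_pta` and `us_guided` both
#'     = F49A − F49G.}
#'   \item{interventional}{base = arithmetic mean of F24B and F19C (the two
#'     interventional base DRGs); `transfusion_pta` = F24A − F24B;
#'     `us_guided` = F19A − F19C.}
#'   \item{combined}{weighted blend (default 1:2) of the diagnostic and
#'     interventional values, entry by entry.}
#' }
#' In every scenario `endovascular_surgery` is the flat F08E reimbursement
#' and `antibiotics` the flat T61B reimbursement (distinct DRGs).
#'
#' @param drg_table named numeric vector of reimbursements; must contain
#'   codes F49G, F49A, F24B, F24A, F19C, F19A, F08E, T61B.
#' @param scenario_id one of [scenario_ids()].
#' @param w_diag,w_interv weights for the combined blend (default 1:2).
#' @return an object of class `vcd_cost_schedule` with fields
#'   `scenario_id`, `base_cath_cost`, and `treatment_cost` (named numeric,
#'   one entry per [treatment_keys()]).
#' @export
#' @examples
#' sched <- build_cost_schedule(paper_fixture()$drg_table, "combined")
#' sched$treatment_cost[["transfusion_pta"]]  # 3522.26
build_cost_schedule <- function(drg_table, scenario_id,
                                w_diag = 1, w_interv = 2) {
  check_scenario(scenario_id)
  missing <- setdiff(.schedule_codes, names(drg_table))
  if (length(missing) > 0L) {
    stop_ctx("DRG table is missing code(s): %s", paste(missing, collapse = ", "))
  }
  d <- as.list(drg_table[.schedule_codes])
  flat <- c(endovascular_surgery = d$F08E, antibiotics = d$T61B)
  diag <- list(
    base = d$F49G,
    tc = c(transfusion_pta = drg_difference(d$F49A, d$F49G),
           us_guided = drg_difference(d$F49A, d$F49G), flat))
  interv <- list(
    base = mean(c(d$F24B, d$F19C)),
    tc = c(transfusion_pta = drg_difference(d$F24A, d$F24B),
           us_guided = drg_difference(d$F19A, d$F19C), flat))
  part <- switch(scenario_id,
    diagnostic = diag,
    interventional = interv,
    combined = list(
      base = combined_value(diag$base, interv$base, w_diag, w_interv),
      tc = combined_value(diag$tc, interv$tc, w_diag, w_interv)))
  structure(list(scenario_id = scenario_id,
                 base_cath_cost = part$base,
                 treatment_cost = part$tc[treatment_keys()]),
            class = "vcd_cost_schedule")
}

#' @export
print.vcd_cost_schedule <- function(x, ...) {
  cat(sprintf("<vcd_cost_schedule> %s: base %.2f EUR\n", x$scenario_id,
              x$base_cath_cost))
  print(round(x$treatment_cost, 2))
  invisible(x)
}

# schedule implied by a full parameterization
schedule_for <- function(params) {
  build_cost_schedule(params$drg_table, params$scenario_id,
                      params$weight_diag, params$weight_interv)
}
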