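pricing_result <- function(method, premium, inputs_echo) {
  structure(list(method = method, premium = premium,
                 inputs_echo = inputs_echo),
            class = "vcd_pricing")
}

#' @export
print.vcd_pricing <- function(x, ...) {
  cat(sprintf("<vcd_pricing> %s: premium EUR %s per catheterization\n",
              x$method, fmt_euro(x$premium)))
  invisible(x)
}

#' Cost-saving value-based premium
#'
#' The maximum add-on price at which adopting a device does not raise payer
#' spending: the complication-attributable cost of the reference device
#' minus that of the (improved) device, both evaluated with failure-branch
#' mixing on the same schedule. By linearity this equals the
#' [savings_by_complication()] sum over the complications the device
#' eliminates.
#'
#' @param device the improved [strategy_spec()].
#' @param reference_device the established comparator device.
#' @param schedule a [build_cost_schedule()] result.
#' @return a `vcd_pricing` result with `method = "cost_saving"`.
#' @export
cost_saving_premium <- function(device, reference_device, schedule) {
  c_dev <- evaluate_strategy(device, schedule)$complication_cost
  c_ref <- evaluate_strategy(reference_device, schedule)$complication_cost
  pricing_result("cost_saving", c_ref - c_dev,
                 list(device = device$name,
                      reference = reference_device$name,
                      complication_cost_device = c_dev,
                      complication_cost_reference = c_ref))
}

#' Efficiency-frontier value-based premium
#'
#' Values averted complications at the cost-effectiveness of the current
#' treatment standard (the frontier ICER of the scenario where the existing
#' device is not dominated): `premium = frontier_icer * delta_prevented`.
#' Full precision; euro rounding is display-only. The premium is gross of
#' the device's own incremental complication cost; see
#' [cost_saving_premium()] for the cost-neutral bound.
#'
#' @param frontier_icer positive ICER of the frontier strategy (EUR per
#'   averted complication).
#' @param delta_prevented complications averted by the candidate device per
#'   catheterization (>= 0).
#' @return a `vcd_pricing` result with `method = "frontier"`.
#' @export
frontier_premium <- function(frontier_icer, delta_prevented) {
  if (!(is.numeric(frontier_icer) && frontier_icer > 0)) {
    stop_ctx("frontier_icer must be > 0 (got %s)", frontier_icer)
  }
  if (!(is.numeric(delta_prevented) && delta_prevented >= 0)) {
    stop_ctx("delta_prevented must be >= 0 (got %s)", delta_prevented)
  }
  pricing_result("frontier", frontier_icer * delta_prevented,
                 list(frontier_icer = frontier_icer,
                      delta_prevented = delta_prevented))
}

#' Savings from same-day discharge
#'
#' Two views of the value generated by discharging patients on the day of a
#' diagnostic catheterization (made safe by a bleeding-preventing device):
#' \describe{
#'   \item{resource}{the avoidable resource component of the inpatient DRG
#'     (hotel and general-ward costs, roughly EUR 400 per patient).}
#'   \item{reimbursement}{the difference between the inpatient DRG and the
#'     total outpatient fee-schedule reimbursement for the same procedure
#'     (roughly EUR 600).}
#' }
#'
#' @param mode `"resource"` or `"reimbursement"`.
#' @param inpatient_drg inpatient DRG reimbursement (EUR; reimbursement
#'   mode).
#' @param avoidable_component avoidable ward-cost component (EUR; resource
#'   mode).
#' @param outpatient_fee_total summed outpatient fees (EUR; reimbursement
#'   mode; must not exceed `inpatient_drg`).
#' @return a `vcd_pricing` result.
#' @export
same_day_savings <- function(mode = c("resource", "reimbursement"),
                             inpatient_drg = NULL,
                             avoidable_component = NULL,
                             outpatient_fee_total = NULL) {
  mode <- match.arg(mode)
  if (mode == "resource") {
    if (is.null(avoidable_component) || avoidable_component < 0) {
      stop_ctx("resource mode requires avoidable_component >= 0")
    }
    pricing_result("same_day_resource", avoidable_component,
                   list(avoidable_component = avoidable_component))
  } else {
    if (is.null(inpatient_drg) || is.null(outpatient_fee_total) ||
        inpatient_drg < 0 || outpatient_fee_total < 0) {
      stop_ctx("reimbursement mode requires inpatient_drg >= 0 and outpatient_fee_total >= 0")
    }
    if (outpatient_fee_total > inpatient_drg) {
      stop_ctx("outpatient_fee_total (%s) exceeds inpatient_drg (%s)",
               outpatient_fee_total, inpatient_drg)
    }
    pricing_result("same_day_reimbursement",
                   inpatient_drg - outpatient_fee_total,
                   list(inpatient_drg = inpatient_drg,
                        outpatient_fee_total = outpatient_fee_total))
  }
}
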