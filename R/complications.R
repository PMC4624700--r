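#' Access-site complications tracked by the model
#'
#' The decision tree distinguishes six access-site complications of
#' transfemoral catheterization: hematoma (large), retroperitoneal
#' hemorrhage (`rph`), arteriovenous fistula (`avf`), pseudoaneurysm
#' (`psa`), limb ischemia / arterial stenosis (`limb_ischemia`), and
#' access-site infection. The order is fixed and used for all deterministic
#' output.
#'
#' @return character vector of the six complication identifiers, in
#'   canonical order.
#' @export
#' @examples
#' complications()
complications <- function() {
  c("hematoma", "rph", "avf", "psa", "limb_ischemia", "infection")
}

#' Treatment cost keys
#'
#' Each complication treatment maps to one of four cost keys of the cost
#' schedule: `transfusion_pta` (blood transfusion or percutaneous
#' transluminal angioplasty, reimbursed through the higher-weighted
#' catheterization DRG), `us_guided` (ultrasound-guided compression or
#' thrombin/glue treatment, same mechanism), `endovascular_surgery`
#' (endovascular intervention or vascular surgery, distinct DRG), and
#' `antibiotics` (systemic antibiotic treatment of infection, distinct DRG).
#'
#' @return character vector of the four treatment keys.
#' @export
treatment_keys <- function() {
  c("transfusion_pta", "us_guided", "endovascular_surgery", "antibiotics")
}

#' Model scenarios
#'
#' @return character vector of the three supported catheterization
#'   scenarios.
#' @export
scenario_ids <- function() {
  c("diagnostic", "interventional", "combined")
}

check_scenario <- function(scenario_id) {
  if (!(is.character(scenario_id) && length(scenario_id) == 1L &&
        scenario_id %in% scenario_ids())) {
    stop_ctx("unknown scenario_id '%s'; valid ids are: %s",
             paste(scenario_id, collapse = ","),
             paste(scenario_ids(), collapse = ", "))
  }
  scenario_id
}
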