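#' Construct a hemostasis strategy specification
#'
#' A strategy bundles the per-complication marginal probabilities of its
#' device (or compression) branch, the treatment rules that translate
#' complications into costed treatments, and an optional failure arm: with
#' probability `failure_prob` the device fails and the `fallback` strategy's
#' rates and treatment rules apply instead (manual compression in the
#' published model).
#'
#' @param name strategy identifier (e.g. `"MC"`, `"VCD"`).
#' @param rates named numeric vector of complication probabilities
#'   (fractions in \[0, 1\]); names must be exactly [complications()].
#' @param treatments named list, one element per complication, each a
#'   `data.frame` with columns `treatment` (a [treatment_keys()] value) and
#'   `prob` (fraction). Treatments within one complication are independent
#'   events; retroperitoneal hemorrhage carries two independent rules.
#' @param failure_prob probability that the device fails (fraction);
#'   strictly positive values require a `fallback`.
#' @param fallback another `vcd_strategy` applied on device failure; must
#'   itself have `failure_prob = 0`.
#' @return an object of class `vcd_strategy`.
#' @export
strategy_spec <- function(name, rates, treatments, failure_prob = 0,
                          fallback = NULL) {
  spec <- structure(
    list(name = name, rates = rates[complications()],
         treatments = treatments[complications()],
         failure_prob = failure_prob, fallback = fallback),
    class = "vcd_strategy")
  viol <- validate_strategy(spec)
  if (nrow(viol) > 0L) {
    stop_ctx("invalid strategy '%s': %s", name,
             paste(viol$rule, collapse = "; "))
  }
  spec
}

#' @export
print.vcd_strategy <- function(x, ...) {
  cat(sprintf("<vcd_strategy> %s (failure_prob = %g%s)\n", x$name,
              x$failure_prob,
              if (!is.null(x$fallback)) paste0(", fallback = ", x$fallback$name) else ""))
  print(x$rates)
  invisible(x)
}

#' Construct a full model parameterization
#'
#' @param scenario_id one of [scenario_ids()].
#' @param strategies list of [strategy_spec()] objects; at least two (an
#'   intervention and a comparator). The list is named by strategy name.
#' @param drg_table named numeric vector of DRG reimbursements (EUR,
#'   financial year 2010), names are DRG codes.
#' @param weight_diag,weight_interv positive weights used to blend
#'   diagnostic and interventional costs in the combined scenario
#'   (default 1:2, the diagnostic:interventional case mix of the underlying
#'   meta-analysis).
#' @return an object of class `vcd_params`.
#' @export
model_parameters <- function(scenario_id, strategies, drg_table,
                             weight_diag = 1, weight_interv = 2) {
  check_scenario(scenario_id)
  names(strategies) <- vapply(strategies, function(s) s$name, character(1))
  params <- structure(
    list(scenario_id = scenario_id, strategies = strategies,
         drg_table = drg_table, weight_diag = weight_diag,
         weight_interv = weight_interv),
    class = "vcd_params")
  viol <- validate_parameters(params)
  if (nrow(viol) > 0L) {
    stop_ctx("invalid model parameters: %s", paste(viol$rule, collapse = "; "))
  }
  params
}

#' @export
print.vcd_params <- function(x, ...) {
  cat(sprintf("<vcd_params> scenario '%s', strategies: %s; %d DRG codes; weights %g:%g\n",
              x$scenario_id, paste(names(x$strategies), collapse = ", "),
              length(x$drg_table), x$weight_diag, x$weight_interv))
  invisible(x)
}

# ---- fixture: the published parameterization -------------------------------

# Complication rates (fractions per catheterization). AVF rates come from an
# interventional-only pooled analysis and are applied unchanged in all
# scenarios, as in the source tables.
.fixture_rates <- function(scenario_id) {
  r <- switch(scenario_id,
    combined = list(
      VCD = c(hematoma = 0.0456, rph = 0.0379, avf = 0.0083, psa = 0.0160,
              limb_ischemia = 0.0031, infection = 0.0061),
      MC  = c(hematoma = 0.0508, rph = 0.0291, avf = 0.0020, psa = 0.0159,
              limb_ischemia = 0.0000, infection = 0.0022)),
    diagnostic = list(
      VCD = c(hematoma = 0.0420, rph = 0.0440, avf = 0.0083, psa = 0.0090,
              limb_ischemia = 0.0000, infection = 0.0010),
      MC  = c(hematoma = 0.0570, rph = 0.0530, avf = 0.0020, psa = 0.0000,
              limb_ischemia = 0.0000, infection = 0.0010)),
    interventional = list(
      VCD = c(hematoma = 0.0440, rph = 0.0360, avf = 0.0083, psa = 0.0260,
              limb_ischemia = 0.0030, infection = 0.0090),
      MC  = c(hematoma = 0.0480, rph = 0.0240, avf = 0.0020, psa = 0.0250,
              limb_ischemia = 0.0000, infection = 0.0030)))
  lapply(r, function(v) v[complications()])
}

# Treatment rules. Only large hematomas requiring transfusion and the two
# independent RPH treatments carry probabilities < 1; AVF/PSA (US-guided
# compression), limb ischemia (PTA) and infection (antibiotics) are always
# treated.
.fixture_treatments <- function(transfusion_hematoma) {
  rule <- function(treatment, prob) data.frame(treatment = treatment,
                                               prob = prob,
                                               stringsAsFactors = FALSE)
  list(
    hematoma = rule("transfusion_pta", transfusion_hematoma),
    rph = rule(c("transfusion_pta", "endovascular_surgery"), c(0.01, 0.01)),
    avf = rule("us_guided", 1),
    psa = rule("us_guided", 1),
    limb_ischemia = rule("transfusion_pta", 1),
    infection = rule("antibiotics", 1))
}

# DRG reimbursements, EUR, financial year 2010.
.fixture_drg <- function() {
  c(F49G = 1085.33, F49A = 6385.32,   # diagnostic w/o & with major complications
    F24B = 5108.25, F24A = 7741.65,   # PCI w/o & with major complications
    F19C = 4603.30, F19A = 7063.48,   # transluminal intervention w/o & with
    F08E = 6834.49,                   # reconstructive vascular intervention
    T61B = 1735.05)                   # postoperative infection
}

.fixture_failure_prob <- 0.036

#' Published model parameterization
#'
#' Returns the full parameterization of the published decision-tree model
#' for one scenario: the manual compression strategy (`MC`, no failure arm)
#' and the vascular closure device strategy (`VCD`, 3.6 % failure
#' probability with MC as fallback), together with the 2010 DRG table and
#' the 1:2 diagnostic:interventional weighting.
#'
#' All probabilities are stored as fractions (0.0456, never 4.56). Each
#' call returns a fresh, independent copy.
#'
#' @param scenario_id one of [scenario_ids()] (default `"combined"`).
#' @return a [model_parameters()] object.
#' @export
#' @examples
#' p <- paper_fixture("combined")
#' p$strategies$VCD$rates[["hematoma"]]  # 0.0456
paper_fixture <- function(scenario_id = "combined") {
  check_scenario(scenario_id)
  rates <- .fixture_rates(scenario_id)
  mc <- strategy_spec("MC", rates$MC, .fixture_treatments(0.003),
                      failure_prob = 0)
  vcd <- strategy_spec("VCD", rates$VCD, .fixture_treatments(0.002),
                       failure_prob = .fixture_failure_prob, fallback = mc)
  model_parameters(scenario_id, list(mc, vcd), .fixture_drg())
}

# ---- validation ------------------------------------------------------------

violation <- function(field, value, rule) {
  data.frame(field = field, value = as.character(value), rule = rule,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(field = character(), value = character(), rule = character(),
             stringsAsFactors = FALSE)
}

validate_rates <- function(rates, prefix) {
  v <- no_violations()
  missing <- setdiff(complications(), names(rates))
  if (length(missing) > 0L) {
    v <- rbind(v, violation(prefix, paste(missing, collapse = ","),
                            "all six complications must be present"))
  }
  for (c_id in intersect(complications(), names(rates))) {
    r <- rates[[c_id]]
    if (!is_prob(r)) {
      v <- rbind(v, violation(paste0(prefix, ".", c_id), r,
                              "complication rate must be a fraction in [0, 1]"))
    }
  }
  v
}

validate_strategy <- function(spec, prefix = spec$name) {
  v <- validate_rates(spec$rates, paste0(prefix, ".rates"))
  for (c_id in intersect(complications(), names(spec$treatments))) {
    rules <- spec$treatments[[c_id]]
    if (is.null(rules)) next
    bad_key <- setdiff(rules$treatment, treatment_keys())
    if (length(bad_key) > 0L) {
      v <- rbind(v, violation(paste0(prefix, ".treatments.", c_id),
                              paste(bad_key, collapse = ","),
                              "unknown treatment key"))
    }
    for (i in seq_len(nrow(rules))) {
      if (!is_prob(rules$prob[i])) {
        v <- rbind(v, violation(
          paste0(prefix, ".treatments.", c_id, ".", rules$treatment[i]),
          rules$prob[i], "treatment probability must be a fraction in [0, 1]"))
      }
    }
  }
  if (!is_prob(spec$failure_prob)) {
    v <- rbind(v, violation(paste0(prefix, ".failure_prob"), spec$failure_prob,
                            "failure probability must be a fraction in [0, 1]"))
  } else if (spec$failure_prob > 0 && is.null(spec$fallback)) {
    v <- rbind(v, violation(paste0(prefix, ".fallback"), "NULL",
                            "failure_prob > 0 requires a fallback strategy"))
  }
  if (!is.null(spec$fallback)) {
    if (!identical(spec$fallback$failure_prob, 0) &&
        !(is.numeric(spec$fallback$failure_prob) && spec$fallback$failure_prob == 0)) {
      v <- rbind(v, violation(paste0(prefix, ".fallback.failure_prob"),
                              spec$fallback$failure_prob,
                              "fallback must itself have failure_prob = 0"))
    }
    v <- rbind(v, validate_strategy(spec$fallback,
                                    paste0(prefix, ".fallback")))
  }
  v
}

#' Validate a model parameterization
#'
#' Checks every type invariant (probabilities in \[0, 1\], six complications
#' present, failure arm wired to a fallback, non-negative DRG
#' reimbursements, positive weights, at least two strategies) and reports
#' all violations. Validation never raises; an empty data frame means the
#' parameters are valid.
#'
#' @param params a [model_parameters()] object (or a bare list with the same
#'   fields).
#' @return data frame with columns `field`, `value`, `rule`; zero rows iff
#'   valid.
#' @export
validate_parameters <- function(params) {
  v <- no_violations()
  if (!(params$scenario_id %in% scenario_ids())) {
    v <- rbind(v, violation("scenario_id", params$scenario_id,
                            "unknown scenario"))
  }
  if (length(params$strategies) < 2L) {
    v <- rbind(v, violation("strategies", length(params$strategies),
                            "at least two strategies required"))
  }
  for (s in params$strategies) v <- rbind(v, validate_strategy(s))
  drg <- params$drg_table
  if (anyDuplicated(names(drg)) > 0L) {
    v <- rbind(v, violation("drg_table", names(drg)[duplicated(names(drg))][1],
                            "DRG codes must be unique"))
  }
  for (code in names(drg)) {
    if (!is.numeric(drg[[code]]) || is.na(drg[[code]]) || drg[[code]] < 0) {
      v <- rbind(v, violation(paste0("drg_table.", code), drg[[code]],
                              "reimbursement must be >= 0"))
    }
  }
  for (w in c("weight_diag", "weight_interv")) {
    if (!is.numeric(params[[w]]) || length(params[[w]]) != 1L ||
        is.na(params[[w]]) || params[[w]] <= 0) {
      v <- rbind(v, violation(w, params[[w]], "weight must be > 0"))
    }
  }
  v
}

# ---- file I/O --------------------------------------------------------------

strategy_to_list <- function(s) {
  list(name = s$name,
       rates = as.list(s$rates),
       treatments = lapply(s$treatments, function(df) {
         lapply(seq_len(nrow(df)), function(i)
           list(treatment = df$treatment[i], prob = df$prob[i]))
       }),
       failure_prob = s$failure_prob,
       fallback = if (is.null(s$fallback)) NULL else s$fallback$name)
}

#' Write a model parameterization to a JSON configuration file
#'
#' The file stores probabilities as fractions (`"units": "fraction"`),
#' strategies with their rates, treatment rules and failure arm (fallback
#' referenced by name), the DRG table, and the scenario weights. Decimal
#' separator is always the dot. [load_model_config()] round-trips the file
#' back to an identical object.
#'
#' @param params a [model_parameters()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, path) {
  doc <- list(
    scenario_id = params$scenario_id,
    units = "fraction",
    weight_diag = params$weight_diag,
    weight_interv = params$weight_interv,
    drg_table = as.list(params$drg_table),
    strategies = lapply(unname(params$strategies), strategy_to_list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

num_or_stop <- function(x, field) {
  if (is.null(x) || !is.numeric(x) || is.na(suppressWarnings(as.numeric(x)))) {
    stop_ctx("config field '%s' must be numeric, got '%s'", field,
             paste(x, collapse = ","))
  }
  as.numeric(x)
}

#' Load a model parameterization from a JSON configuration file
#'
#' Accepts the schema written by [write_model_config()]. A top-level
#' `"units"` flag of `"percent"` declares that all probabilities (rates,
#' treatment probabilities, failure probabilities) are percentages and
#' converts them to fractions on load; `"fraction"` (the default written by
#' this package) takes them as-is. Missing files, missing complications,
#' unknown fallback references and non-numeric probabilities raise distinct
#' errors naming the offending field.
#'
#' @param path path to a JSON configuration.
#' @return a [model_parameters()] object.
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop_ctx("config file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  units <- doc$units
  if (is.null(units)) units <- "fraction"
  if (!(units %in% c("fraction", "percent"))) {
    stop_ctx("config 'units' must be 'fraction' or 'percent', got '%s'", units)
  }
  scale <- if (units == "percent") 0.01 else 1
  if (is.null(doc$strategies) || length(doc$strategies) < 1L) {
    stop_ctx("config has no strategies")
  }
  parse_strategy <- function(sd) {
    if (is.null(sd$name)) stop_ctx("strategy without a 'name' field")
    rates_in <- sd$rates
    missing <- setdiff(complications(), names(rates_in))
    if (length(missing) > 0L) {
      stop_ctx("strategy '%s': missing complication rate(s): %s", sd$name,
               paste(missing, collapse = ", "))
    }
    rates <- vapply(complications(), function(c_id)
      num_or_stop(rates_in[[c_id]],
                  paste0(sd$name, ".rates.", c_id)) * scale,
      numeric(1))
    treatments <- lapply(complications(), function(c_id) {
      rules <- sd$treatments[[c_id]]
      if (is.null(rules)) {
        return(data.frame(treatment = character(), prob = numeric(),
                          stringsAsFactors = FALSE))
      }
      data.frame(
        treatment = vapply(rules, function(r) as.character(r$treatment),
                           character(1)),
        prob = vapply(seq_along(rules), function(i)
          num_or_stop(rules[[i]]$prob,
                      paste0(sd$name, ".treatments.", c_id)) * scale,
          numeric(1)),
        stringsAsFactors = FALSE)
    })
    names(treatments) <- complications()
    fb_name <- sd$fallback
    if (length(fb_name) == 0L) fb_name <- NULL  # JSON null in any encoding
    list(name = sd$name, rates = rates, treatments = treatments,
         failure_prob = num_or_stop(
           if (is.null(sd$failure_prob)) 0 else sd$failure_prob,
           paste0(sd$name, ".failure_prob")) * scale,
         fallback_name = fb_name)
  }
  parsed <- lapply(doc$strategies, parse_strategy)
  names(parsed) <- vapply(parsed, `[[`, character(1), "name")
  strategies <- lapply(parsed, function(p) {
    fb <- NULL
    if (!is.null(p$fallback_name)) {
      ref <- parsed[[p$fallback_name]]
      if (is.null(ref)) {
        stop_ctx("strategy '%s': fallback '%s' not defined in config",
                 p$name, p$fallback_name)
      }
      fb <- strategy_spec(ref$name, ref$rates, ref$treatments,
                          failure_prob = ref$failure_prob)
    }
    strategy_spec(p$name, p$rates, p$treatments,
                  failure_prob = p$failure_prob, fallback = fb)
  })
  drg <- vapply(doc$drg_table, function(x)
    num_or_stop(x, "drg_table"), numeric(1))
  model_parameters(
    doc$scenario_id, strategies, drg,
    weight_diag = if (is.null(doc$weight_diag)) 1 else
      num_or_stop(doc$weight_diag, "weight_diag"),
    weight_interv = if (is.null(doc$weight_interv)) 2 else
      num_or_stop(doc$weight_interv, "weight_interv"))
}

#' Read a DRG reimbursement table from CSV
#'
#' Expects columns `code` and `reimbursement_eur`. A fixture mirroring the
#' published 2010 table ships at
#' `system.file("extdata", "drg_2010.csv", package = "vcdvalue")`.
#'
#' @param path CSV file path.
#' @return named numeric vector of reimbursements (EUR), names = DRG codes.
#' @export
read_drg_csv <- function(path) {
  if (!file.exists(path)) stop_ctx("DRG table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "reimbursement_eur")
  if (!all(need %in% names(df))) {
    stop_ctx("DRG CSV must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$code) > 0L) {
    stop_ctx("duplicate DRG code in %s: %s", path,
             df$code[duplicated(df$code)][1])
  }
  stats::setNames(as.numeric(df$reimbursement_eur), df$code)
}
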