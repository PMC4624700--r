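#' Configuration for the synthetic parameter generator
#'
#' The generator emulates the structure of the published inputs — six
#' complication probabilities per strategy branch, fixture-shaped treatment
#' rules, a device-failure probability with a manual-compression-style
#' fallback, and a DRG table in which every higher-weighted DRG dominates
#' its lower-weighted partner — without calibrating to any real data. The
#' defaults keep instances in the published regime: complication rates stay
#' below 0.2 (all published rates are below 6 %), costs span the published
#' DRG range, and failure probabilities stay below 0.1 (published: 3.6 %).
#'
#' @param seed integer RNG seed; generation is a pure function of the
#'   configuration including the seed.
#' @param rate_upper_bound upper bound for complication rates (default 0.2).
#' @param cost_range two-element EUR interval for DRG reimbursements
#'   (default `c(500, 10000)`).
#' @param failure_prob_range two-element interval for the device failure
#'   probability (default `c(0, 0.1)`).
#' @return an object of class `vcd_generator_config`.
#' @export
generator_config <- function(seed, rate_upper_bound = 0.2,
                             cost_range = c(500, 10000),
                             failure_prob_range = c(0, 0.1)) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            rate_upper_bound > 0, rate_upper_bound <= 1,
            length(cost_range) == 2L, cost_range[1] >= 0,
            cost_range[1] <= cost_range[2],
            length(failure_prob_range) == 2L, failure_prob_range[1] >= 0,
            failure_prob_range[2] <= 1,
            failure_prob_range[1] <= failure_prob_range[2])
  structure(list(seed = as.integer(seed),
                 rate_upper_bound = rate_upper_bound,
                 cost_range = cost_range,
                 failure_prob_range = failure_prob_range),
            class = "vcd_generator_config")
}

random_treatments <- function() {
  rule <- function(treatment, prob) data.frame(treatment = treatment,
                                               prob = prob,
                                               stringsAsFactors = FALSE)
  list(
    hematoma = rule("transfusion_pta", stats::runif(1)),
    rph = rule(c("transfusion_pta", "endovascular_surgery"), stats::runif(2)),
    avf = rule("us_guided", stats::runif(1)),
    psa = rule("us_guided", stats::runif(1)),
    limb_ischemia = rule("transfusion_pta", stats::runif(1)),
    infection = rule("antibiotics", stats::runif(1)))
}

#' Draw a random, structurally valid parameterization
#'
#' Two strategies: a comparator with no failure arm and a device whose
#' failure probability is drawn from the configured range (falling back to
#' the comparator when positive). Complication rates are uniform on
#' `[0, rate_upper_bound]`, treatment probabilities uniform on `[0, 1]`,
#' and the DRG table guarantees `higher >= lower` within each DRG pair by
#' drawing a non-negative increment. Every draw passes
#' [validate_parameters()]; the same configuration yields the same output.
#'
#' @param config a [generator_config()].
#' @return a [model_parameters()] object (scenario `"combined"`).
#' @export
random_parameters <- function(config) {
  stopifnot(inherits(config, "vcd_generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  draw_rates <- function() {
    stats::setNames(stats::runif(6, 0, config$rate_upper_bound),
                    complications())
  }
  comparator <- strategy_spec("comparator", draw_rates(),
                              random_treatments(), failure_prob = 0)
  f <- stats::runif(1, config$failure_prob_range[1],
                    config$failure_prob_range[2])
  device <- strategy_spec("device", draw_rates(), random_treatments(),
                          failure_prob = f,
                          fallback = if (f > 0) comparator else NULL)
  lo <- config$cost_range[1]
  hi <- config$cost_range[2]
  base_draw <- function() stats::runif(1, lo, hi)
  upgrade <- function(x) min(x + stats::runif(1, 0, hi - x), hi)
  f49g <- base_draw(); f24b <- base_draw(); f19c <- base_draw()
  drg <- c(F49G = f49g, F49A = upgrade(f49g),
           F24B = f24b, F24A = upgrade(f24b),
           F19C = f19c, F19A = upgrade(f19c),
           F08E = base_draw(), T61B = base_draw())
  model_parameters("combined", list(comparator, device), drg)
}

#' Symmetric relative uncertainty ranges around point estimates
#'
#' Builds a range for every effect parameter of a parameterization —
#' complication rates, treatment probabilities and failure probabilities —
#' as `[max(0, p(1-w)), min(1, p(1+w))]`. A stand-in for unavailable
#' published confidence limits; by construction each point estimate lies in
#' its range, and a zero rate yields the degenerate range `[0, 0]`. The
#' output is deterministic; `seed` is accepted for interface stability and
#' currently unused.
#'
#' @param params a [model_parameters()] object.
#' @param relative_width relative half-width `w` in `(0, 1]` (e.g. 0.3 for
#'   ±30 %).
#' @param seed unused; reserved.
#' @return data frame of ranges as produced by [parameter_range()].
#' @export
ci_ranges_around <- function(params, relative_width, seed = NULL) {
  if (!(is.numeric(relative_width) && relative_width > 0 &&
        relative_width <= 1)) {
    stop_ctx("relative_width must lie in (0, 1]")
  }
  targets <- character()
  for (nm in names(params$strategies)) {
    s <- params$strategies[[nm]]
    targets <- c(targets, paste0(nm, ".rates.", complications()))
    for (c_id in complications()) {
      rl <- s$treatments[[c_id]]
      if (!is.null(rl) && nrow(rl) > 0L) {
        targets <- c(targets,
                     paste0(nm, ".treatments.", c_id, ".", rl$treatment))
      }
    }
    if (s$failure_prob > 0) targets <- c(targets, paste0(nm, ".failure_prob"))
  }
  do.call(rbind, lapply(targets, function(tg) {
    p <- get_parameter(params, tg)
    parameter_range(tg, max(0, p * (1 - relative_width)),
                    min(1, p * (1 + relative_width)))
  }))
}
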