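test_that("parameter paths resolve, substitute, and propagate into the failure arm", {
  p <- paper_fixture("combined")
  expect_equal(get_parameter(p, "MC.rates.hematoma"), 0.0508)
  expect_equal(get_parameter(p, "VCD.treatments.hematoma.transfusion_pta"),
               0.002)
  expect_equal(get_parameter(p, "VCD.failure_prob"), 0.036)
  expect_error(get_parameter(p, "VCD.rates.gout"), "VCD.rates.gout")
  expect_error(get_parameter(p, "ACME.rates.hematoma"), "ACME")

  p2 <- set_parameter(p, "MC.rates.hematoma", 0.10)
  expect_equal(get_parameter(p2, "MC.rates.hematoma"), 0.10)
  # the VCD failure arm carries MC's parameters, so it must follow
  expect_equal(p2$strategies$VCD$fallback$rates[["hematoma"]], 0.10)
  # and the input is untouched
  expect_equal(get_parameter(p, "MC.rates.hematoma"), 0.0508)
  expect_error(set_parameter(p, "MC.rates.hematoma", 1.7), "probability")
})

test_that("one-way DSA endpoints equal direct substitution, ceteris paribus", {
  p <- paper_fixture("combined")
  snapshot <- paper_fixture("combined")
  ranges <- rbind(
    parameter_range("MC.rates.hematoma", 0.03, 0.08),
    parameter_range("VCD.rates.psa", 0.010, 0.022),
    parameter_range("MC.treatments.hematoma.transfusion_pta", 0.001, 0.006),
    parameter_range("VCD.failure_prob", 0.01, 0.08))
  rows <- one_way_dsa(p, ranges, outcome = "incremental_cost")
  expect_identical(nrow(rows), 4L)
  expect_identical(p, snapshot)  # no mutation

  direct <- function(target, value) {
    q <- set_parameter(p, target, value)
    sched <- build_cost_schedule(q$drg_table, q$scenario_id)
    evaluate_strategy(q$strategies$VCD, sched)$total_cost -
      evaluate_strategy(q$strategies$MC, sched)$total_cost
  }
  for (i in seq_len(nrow(ranges))) {
    expect_equal(rows$outcome_at_low[i],
                 direct(ranges$target[i], ranges$low[i]))
    expect_equal(rows$outcome_at_high[i],
                 direct(ranges$target[i], ranges$high[i]))
    expect_equal(rows$spread[i],
                 abs(rows$outcome_at_high[i] - rows$outcome_at_low[i]))
  }

  # degenerate range has zero spread; a single live range yields one
  # non-zero row
  degenerate <- parameter_range("MC.rates.hematoma", 0.0508, 0.0508)
  expect_equal(one_way_dsa(p, degenerate)$spread, 0)
  mixed <- rbind(degenerate, parameter_range("VCD.rates.psa", 0.01, 0.022))
  spreads <- one_way_dsa(p, mixed)$spread
  expect_identical(sum(spreads > 0), 1L)

  expect_error(one_way_dsa(p, parameter_range("MC.rates.hematoma", 0.2, 0.3)),
               "outside range")
})

test_that("ICER outcome is flagged, not computed, where dominance makes it meaningless", {
  p <- paper_fixture("combined")  # VCD dominated at the point estimates
  rows <- one_way_dsa(p, parameter_range("MC.rates.hematoma", 0.04, 0.06),
                      outcome = "icer")
  expect_true(is.na(rows$outcome_at_low) || is.na(rows$outcome_at_high))
  expect_match(rows$note, "dominated")

  pd <- paper_fixture("diagnostic")  # tradeoff: ICER defined
  rows_d <- one_way_dsa(pd, parameter_range("MC.rates.hematoma", 0.05, 0.06),
                        outcome = "icer")
  expect_false(any(is.na(c(rows_d$outcome_at_low, rows_d$outcome_at_high))))
  expect_identical(rows_d$note, "")
})

test_that("tornado ordering sorts by spread with a lexicographic tie-break", {
  rows <- data.frame(target = c("b", "a", "c"),
                     outcome_at_low = c(0, 0, 0),
                     outcome_at_high = c(2, 5, 1),
                     spread = c(2, 5, 1), note = "",
                     stringsAsFactors = FALSE)
  expect_identical(tornado_order(rows)$spread, c(5, 2, 1))
  ties <- data.frame(target = c("z.path", "a.path", "m.path"),
                     outcome_at_low = 0, outcome_at_high = 1,
                     spread = 1, note = "", stringsAsFactors = FALSE)
  expect_identical(tornado_order(ties)$target,
                   c("a.path", "m.path", "z.path"))
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    rnd <- data.frame(target = replicate(n, paste(sample(letters, 6),
                                                  collapse = "")),
                      outcome_at_low = 0, outcome_at_high = 0,
                      spread = sample(round(runif(n, 0, 10), 1), n,
                                      replace = TRUE),
                      note = "", stringsAsFactors = FALSE)
    rnd$outcome_at_high <- rnd$spread
    expect_identical(tornado_order(rnd),
                     rnd[order(-rnd$spread, rnd$target), ])
  }
})

test_that("incremental cost extremes occur at range endpoints (linearity)", {
  set.seed(57)
  p <- random_parameters(generator_config(77L))
  outcome_at <- function(target, value) {
    q <- set_parameter(p, target, value)
    sched <- build_cost_schedule(q$drg_table, q$scenario_id)
    evaluate_strategy(q$strategies$device, sched)$total_cost -
      evaluate_strategy(q$strategies$comparator, sched)$total_cost
  }
  for (target in c("comparator.rates.hematoma", "device.rates.psa",
                   "device.treatments.rph.transfusion_pta")) {
    point <- get_parameter(p, target)
    lo <- max(0, point - 0.05)
    hi <- min(1, point + 0.05)
    grid_vals <- vapply(seq(lo, hi, length.out = 41), function(v)
      outcome_at(target, v), numeric(1))
    row <- one_way_dsa(p, parameter_range(target, lo, hi),
                       intervention = "device", comparator = "comparator")
    expect_equal(min(grid_vals), min(row$outcome_at_low, row$outcome_at_high),
                 tolerance = 1e-9)
    expect_equal(max(grid_vals), max(row$outcome_at_low, row$outcome_at_high),
                 tolerance = 1e-9)
  }
})

test_that("the bundled illustrative ranges load and bracket their point estimates", {
  path <- system.file("extdata", "dsa_ranges_illustrative_synthetic.csv",
                      package = "vcdvalue")
  ranges <- read_ranges_csv(path)
  p <- paper_fixture("combined")
  expect_gt(nrow(ranges), 20)
  for (i in seq_len(nrow(ranges))) {
    point <- get_parameter(p, ranges$target[i])
    expect_gte(point, ranges$low[i])
    expect_lte(point, ranges$high[i])
  }
  rows <- tornado_order(one_way_dsa(p, ranges))
  expect_true(all(diff(rows$spread) <= 1e-12))
})
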