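combined_setup <- function() {
  p <- paper_fixture("combined")
  list(params = p,
       sched = build_cost_schedule(p$drg_table, "combined"))
}

test_that("expected complications is the sum of marginal rates", {
  cs <- combined_setup()
  expect_equal(expected_complications(cs$params$strategies$MC$rates), 0.100)
  zero <- setNames(rep(0, 6), complications())
  expect_equal(expected_complications(zero), 0)
  set.seed(3)
  for (rep in 1:25) {
    r <- setNames(runif(6, 0, 0.2), sample(complications()))
    expect_equal(expected_complications(r),
                 sum(vapply(complications(), function(c_id) r[[c_id]],
                            numeric(1))))
  }
  expect_error(expected_complications(zero[-1]), "hematoma")
})

test_that("complication-attributable cost matches text value and brute-force oracle", {
  cs <- combined_setup()
  mc <- cs$params$strategies$MC
  cost <- expected_complication_cost(mc$rates, mc$treatments, cs$sched)
  expect_equal(round(cost, 2), 68.35)  # prints as EUR 68
  zero <- setNames(rep(0, 6), complications())
  expect_equal(expected_complication_cost(zero, mc$treatments, cs$sched), 0)
  set.seed(5)
  for (rep in 1:10) {
    p <- random_parameters(generator_config(rep))
    s <- p$strategies$comparator
    expect_equal(
      expected_complication_cost(s$rates, s$treatments, cs$sched),
      oracle_branch(s$rates, s$treatments, cs$sched)$complication_cost,
      tolerance = 1e-9)
  }
  bad <- mc
  bad$treatments$hematoma$treatment <- "leeches"
  expect_error(expected_complication_cost(bad$rates, bad$treatments, cs$sched),
               "leeches")
})

test_that("strategy evaluation mixes the failure arm and reproduces VCD results", {
  cs <- combined_setup()
  vcd <- evaluate_strategy(cs$params$strategies$VCD, cs$sched)
  expect_equal(round_compl(vcd$expected_complications), 0.116)
  expect_equal(round_euro(vcd$total_cost), 3706)
  expect_equal(round_euro(vcd$complication_cost), 107)
  expect_equal(vcd$total_cost, cs$sched$base_cath_cost + vcd$complication_cost)

  # mixing identities at the degenerate failure probabilities
  spec <- cs$params$strategies$VCD
  spec0 <- spec; spec0$failure_prob <- 0; spec0$fallback <- NULL
  pure <- evaluate_strategy(spec0, cs$sched)
  spec_f0 <- spec; spec_f0$failure_prob <- 0
  expect_equal(evaluate_strategy(spec_f0, cs$sched)$total_cost,
               pure$total_cost)
  spec_f1 <- spec; spec_f1$failure_prob <- 1
  fb <- evaluate_strategy(spec$fallback, cs$sched)
  expect_equal(evaluate_strategy(spec_f1, cs$sched)$total_cost, fb$total_cost)
  expect_equal(evaluate_strategy(spec_f1, cs$sched)$expected_complications,
               fb$expected_complications)

  spec_bad <- spec; spec_bad$fallback <- NULL
  expect_error(evaluate_strategy(spec_bad, cs$sched), "fallback")
})

test_that("mixed results are convex combinations of the two branches", {
  cs <- combined_setup()
  set.seed(17)
  for (rep in 1:10) {
    p <- random_parameters(generator_config(100 + rep))
    dev <- p$strategies$device
    if (dev$failure_prob == 0) next
    mixed <- evaluate_strategy(dev, cs$sched)
    pure_dev <- dev; pure_dev$failure_prob <- 0; pure_dev$fallback <- NULL
    lo_hi <- function(field) {
      vals <- c(evaluate_strategy(pure_dev, cs$sched)[[field]],
                evaluate_strategy(dev$fallback, cs$sched)[[field]])
      expect_gte(mixed[[field]], min(vals) - 1e-12)
      expect_lte(mixed[[field]], max(vals) + 1e-12)
    }
    lo_hi("expected_complications")
    lo_hi("complication_cost")
    lo_hi("total_cost")
  }
})

test_that("expected cost is linear in each rate and monotone in device rates", {
  cs <- combined_setup()
  vcd <- cs$params$strategies$VCD
  base_cost <- expected_complication_cost(vcd$rates, vcd$treatments, cs$sched)
  for (c_id in complications()) {
    doubled <- vcd$rates
    doubled[[c_id]] <- min(1, 2 * doubled[[c_id]])
    new_cost <- expected_complication_cost(doubled, vcd$treatments, cs$sched)
    zeroed <- vcd$rates; zeroed[[c_id]] <- 0
    contrib <- base_cost -
      expected_complication_cost(zeroed, vcd$treatments, cs$sched)
    expect_equal(new_cost - base_cost, contrib, tolerance = 1e-9)
  }
  # lowering any device-branch rate never increases either output
  full <- evaluate_strategy(vcd, cs$sched)
  for (c_id in complications()) {
    lowered <- make_hypothetical(vcd, setNames(0.4, c_id))
    res <- evaluate_strategy(lowered, cs$sched)
    expect_lte(res$expected_complications, full$expected_complications)
    expect_lte(res$total_cost, full$total_cost)
  }
})

test_that("incremental analysis classifies dominance and signs the ICER as published", {
  cs <- combined_setup()
  mc <- evaluate_strategy(cs$params$strategies$MC, cs$sched)
  vcd <- evaluate_strategy(cs$params$strategies$VCD, cs$sched)
  inc <- incremental_analysis(vcd, mc)
  expect_identical(inc$status, "dominated")
  expect_equal(round_euro(inc$delta_cost), 39)
  expect_true(is.na(inc$icer))

  expect_identical(incremental_analysis(mc, mc)$status, "equivalent")
  expect_equal(incremental_analysis(mc, mc)$delta_cost, 0)

  pd <- paper_fixture("diagnostic")
  sd <- build_cost_schedule(pd$drg_table, "diagnostic")
  inc_d <- incremental_analysis(
    evaluate_strategy(pd$strategies$VCD, sd),
    evaluate_strategy(pd$strategies$MC, sd))
  expect_identical(inc_d$status, "tradeoff")
  expect_gt(inc_d$icer, 0)  # paying for prevention
  expect_equal(round_euro(inc_d$icer), 9142)

  # antisymmetry: swapping the roles negates deltas and flips dominance
  swapped <- incremental_analysis(mc, vcd)
  expect_equal(swapped$delta_cost, -inc$delta_cost)
  expect_equal(swapped$delta_prevented, -inc$delta_prevented)
  expect_identical(swapped$status, "dominant")
})

test_that("dominance classification matches the sign-quadrant oracle on random pairs", {
  set.seed(29)
  sched <- structure(list(scenario_id = "combined", base_cath_cost = 1000,
                          treatment_cost = setNames(rep(1000, 4),
                                                    treatment_keys())),
                     class = "vcd_cost_schedule")
  mk <- function(e, cc) structure(
    list(strategy_name = "x", expected_complications = e,
         complication_cost = cc, total_cost = 1000 + cc),
    class = "vcd_strategy_result")
  for (rep in 1:200) {
    a <- mk(runif(1, 0, 0.5), runif(1, 0, 300))
    b <- if (rep %% 10 == 0) a else mk(runif(1, 0, 0.5), runif(1, 0, 300))
    inc <- incremental_analysis(a, b)
    expect_identical(inc$status,
                     oracle_status(a$total_cost - b$total_cost,
                                   b$expected_complications -
                                     a$expected_complications))
    if (inc$status == "tradeoff") {
      expect_equal(inc$icer, inc$delta_cost / inc$delta_prevented)
    } else {
      expect_true(is.na(inc$icer))
    }
  }
})
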