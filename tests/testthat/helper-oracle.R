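# Brute-force oracles, independent of the package's evaluation path.
#
# oracle_evaluate enumerates the full outcome tree explicitly: failure
# branch x presence/absence of each complication x applied/not-applied for
# each treatment rule, and computes expectations by explicit summation over
# all joint outcomes. It never uses the linearity shortcuts of the
# implementation.

oracle_branch <- function(rates, rules, schedule) {
  c_ids <- complications()
  flat <- do.call(rbind, lapply(c_ids, function(c_id) {
    rl <- rules[[c_id]]
    if (is.null(rl) || nrow(rl) == 0L) return(NULL)
    data.frame(complication = c_id, treatment = rl$treatment, prob = rl$prob,
               stringsAsFactors = FALSE)
  }))
  n_c <- length(c_ids)
  n_t <- if (is.null(flat)) 0L else nrow(flat)
  grid <- as.matrix(expand.grid(rep(list(0:1), n_c + n_t)))
  pres <- grid[, seq_len(n_c), drop = FALSE]
  appl <- grid[, n_c + seq_len(n_t), drop = FALSE]
  r <- as.numeric(rates[c_ids])
  p_pres <- apply(pres, 1, function(x) prod(ifelse(x == 1, r, 1 - r)))
  if (n_t > 0L) {
    pt <- flat$prob
    p_appl <- apply(appl, 1, function(x) prod(ifelse(x == 1, pt, 1 - pt)))
    cost_t <- schedule$treatment_cost[flat$treatment]
    comp_idx <- match(flat$complication, c_ids)
    cost <- vapply(seq_len(nrow(grid)), function(i) {
      sum(cost_t * appl[i, ] * pres[i, comp_idx])
    }, numeric(1))
  } else {
    p_appl <- rep(1, nrow(grid))
    cost <- rep(0, nrow(grid))
  }
  p <- p_pres * p_appl
  list(expected_complications = sum(p * rowSums(pres)),
       complication_cost = sum(p * cost))
}

oracle_evaluate <- function(spec, schedule) {
  f <- spec$failure_prob
  dev <- oracle_branch(spec$rates, spec$treatments, schedule)
  if (f > 0) {
    fb <- oracle_branch(spec$fallback$rates, spec$fallback$treatments,
                        schedule)
    e <- (1 - f) * dev$expected_complications + f * fb$expected_complications
    cc <- (1 - f) * dev$complication_cost + f * fb$complication_cost
  } else {
    e <- dev$expected_complications
    cc <- dev$complication_cost
  }
  list(expected_complications = e, complication_cost = cc,
       total_cost = schedule$base_cath_cost + cc)
}

# four-quadrant sign oracle for dominance classification
oracle_status <- function(delta_cost, delta_prevented, tol = 1e-12) {
  if (abs(delta_cost) <= tol && abs(delta_prevented) <= tol) return("equivalent")
  if (delta_cost < -tol && delta_prevented > tol) return("dominant")
  if (delta_cost > tol && delta_prevented < -tol) return("dominated")
  "tradeoff"
}
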