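test_that("discounting matches closed forms and never inflates totals", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03, tolerance = 1e-9)
  expect_equal(discount_factor(6, 0.03), 1.03^-0.5, tolerance = 1e-9)
  expect_error(discount_factor(-1, 0.03), ">= 0")

  stream <- runif(144, 0, 100)
  df <- discount_factor(0:143, 0.03)
  expect_lt(sum(stream * df), sum(stream))
  expect_equal(sum(stream * discount_factor(0:143, 0)), sum(stream))
})

test_that("half-cycle correction averages cycle boundaries", {
  occ <- matrix(0.4, nrow = 5, ncol = 8,
                dimnames = list(NULL, health_states()))
  tr <- structure(list(occupancy = occ, arm = "x",
                       resection_cycle = NA_integer_),
                  class = "cohort_trace")
  expect_equal(half_cycle_occupancy(tr), occ[-1, ])

  occ2 <- occ
  occ2[, ] <- 0
  occ2[1, "REMISSION_R0"] <- 1
  occ2[2:5, "DEAD"] <- 1
  tr2 <- structure(list(occupancy = occ2, arm = "x",
                        resection_cycle = NA_integer_),
                   class = "cohort_trace")
  h <- half_cycle_occupancy(tr2)
  expect_equal(unname(h[1, "REMISSION_R0"]), 0.5)
  expect_equal(unname(h[1, "DEAD"]), 0.5)
})

test_that("life-years equal the trapezoidal integral of survival", {
  st <- toy_untreated()
  gen <- toy_general(utility_pf = 1, utility_pall = 1, utility_prog = 1,
                     utility_recovery = 1)
  lt <- flat_life_table(0.1)
  settings <- toy_settings(horizon = 36, discount = 0)
  hz <- toy_hazards(target = "PALLIATIVE")
  trace <- run_cohort(st, gen, hz, settings, lt)
  out <- accumulate_outcomes(trace, st, gen, settings, hz)
  s <- 0.9^(0:36)
  expect_equal(out$life_years, sum((s[-1] + s[-37]) / 2) / 12,
               tolerance = 1e-9)
  # all utilities 1, no disutilities, no discounting: QALYs == life-years
  expect_equal(out$qalys, out$life_years, tolerance = 1e-9)
})

test_that("a year in remission at utility 0.80 yields 0.80 QALYs", {
  st <- toy_untreated()
  gen <- toy_general(utility_pf = 0.8)
  settings <- toy_settings(horizon = 12, discount = 0)
  hz <- toy_hazards(target = "PALLIATIVE")
  trace <- run_cohort(st, gen, hz, settings, flat_life_table(0))
  out <- accumulate_outcomes(trace, st, gen, settings, hz)
  expect_equal(out$qalys, 0.8, tolerance = 1e-12)
  expect_equal(out$life_years, 1, tolerance = 1e-12)
  expect_equal(out$total_cost, 0)
})

test_that("expected toxicity cost is rate times cost per cycle", {
  st <- toy_treated(toxicity = 0.75, cost_tox = 1734)
  gen <- toy_general()
  settings <- toy_settings(horizon = 1, discount = 0)
  settings$chemoradiation_addon <- FALSE
  hz <- toy_hazards()
  trace <- run_cohort(st, gen, hz, settings, flat_life_table(0))
  out <- accumulate_outcomes(trace, st, gen, settings, hz)
  expect_equal(out$total_cost, 0.75 * 1734, tolerance = 1e-9)
  expect_equal(out$trae_cost_month, 0.75 * 1734, tolerance = 1e-9)
})

test_that("an all-dead cohort accrues nothing", {
  occ <- matrix(0, nrow = 13, ncol = 8,
                dimnames = list(NULL, health_states()))
  occ[, "DEAD"] <- 1
  tr <- structure(list(occupancy = occ, flows = NULL, arm = "x",
                       resection_cycle = NA_integer_),
                  class = "cohort_trace")
  st <- toy_untreated()
  gen <- toy_general(cost_eus = 1570.80, cost_inpatient = 5508,
                     cost_palliative = 101388)
  out <- accumulate_outcomes(tr, st, gen, toy_settings(horizon = 12),
                             toy_hazards(pall_death = 0.2,
                                         target = "PALLIATIVE"))
  expect_equal(out$total_cost, 0)
  expect_equal(out$qalys, 0)
  expect_equal(out$life_years, 0)
})

test_that("negative computed state utility raises an error", {
  st <- toy_treated(toxicity = 0.75, disutil_chemo = -0.7,
                    disutil_tox = -0.3)
  gen <- toy_general(utility_pf = 0.8)
  hz <- toy_hazards()
  trace <- run_cohort(st, gen, hz, toy_settings(horizon = 2),
                      flat_life_table(0))
  expect_error(accumulate_outcomes(trace, st, gen, toy_settings(horizon = 2),
                                   hz),
               "negative computed state utility")
})

test_that("frontier on the printed base-case triples matches hand arithmetic", {
  printed <- data.frame(
    strategy = c("natural history", "G-nP", "FOLFIRINOX"),
    total_cost = c(112251, 205161, 240877),
    qalys = c(0.654, 2.54, 2.99))
  ce <- efficiency_frontier(printed, wtp = 1e5)
  # all three strategies stay on the frontier
  expect_equal(ce$frontier$strategy,
               c("natural history", "G-nP", "FOLFIRINOX"))
  expect_equal(length(ce$dominated), 0)
  expect_equal(length(ce$extended_dominated), 0)
  # hand arithmetic on the printed (rounded) values; the published $80,862
  # reflects unrounded model internals
  expect_equal(frontier_icer(ce, "G-nP"), (205161 - 112251) / (2.54 - 0.654),
               tolerance = 1e-12)
  expect_equal(frontier_icer(ce, "FOLFIRINOX"), 35716 / 0.45,
               tolerance = 1e-12)
  expect_equal(round(frontier_icer(ce, "FOLFIRINOX")), 79369)
  icers <- ce$frontier$icer[-1]
  expect_true(all(diff(icers) > 0))
  expect_equal(unname(ce$optimal["100000"]), "FOLFIRINOX")
})

test_that("dominance handling follows the frontier definition", {
  base <- data.frame(strategy = c("A", "B"),
                     total_cost = c(100, 200), qalys = c(1, 2))
  ce0 <- efficiency_frontier(base)
  # higher cost, lower QALYs: dominated and frontier unchanged
  plus <- rbind(base, data.frame(strategy = "C", total_cost = 250,
                                 qalys = 0.5))
  ce1 <- efficiency_frontier(plus)
  expect_equal(ce1$dominated, "C")
  expect_equal(ce1$frontier$strategy, ce0$frontier$strategy)
  expect_equal(ce1$frontier$icer, ce0$frontier$icer)

  # extended dominance: middle strategy with non-monotone ICER chain
  ext <- data.frame(strategy = c("A", "B", "C"),
                    total_cost = c(0, 100, 120),
                    qalys = c(0, 0.5, 2))
  ce2 <- efficiency_frontier(ext)
  expect_equal(ce2$extended_dominated, "B")
  expect_equal(ce2$frontier$strategy, c("A", "C"))

  # exact tie: flagged, deterministic label order
  tie <- data.frame(strategy = c("B", "A"), total_cost = c(100, 100),
                    qalys = c(1, 1))
  ce3 <- efficiency_frontier(tie)
  expect_true(ce3$tie)
  expect_equal(ce3$outcomes$strategy, c("A", "B"))
})

test_that("doubling every cost doubles every frontier ICER", {
  df <- data.frame(strategy = c("A", "B", "C"),
                   total_cost = c(1e5, 2e5, 2.4e5),
                   qalys = c(0.6, 2.5, 3.0))
  ce1 <- efficiency_frontier(df)
  df2 <- df
  df2$total_cost <- 2 * df2$total_cost
  ce2 <- efficiency_frontier(df2)
  expect_equal(ce2$frontier$icer[-1], 2 * ce1$frontier$icer[-1],
               tolerance = 1e-12)
})

test_that("QALYs never exceed life-years in the base case", {
  m <- base_model()
  for (o in m$outcomes) {
    expect_lte(o$qalys, o$life_years)
    expect_gte(o$qalys, 0)
    expect_gte(o$total_cost, 0)
    expect_lte(o$landmark_os_10y, o$landmark_os_5y)
    expect_lte(o$landmark_pfs_10y, o$landmark_pfs_5y)
  }
})
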