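test_that("distribution fits anchor the mean and respect support", {
  # R0 rate: beta on [0, 1], mean at the base value
  s <- fit_distribution("r0_rate", 0.85, 0.40, 0.88)
  expect_equal(s$family, "beta")
  m <- s$pars[["shape1"]] / (s$pars[["shape1"]] + s$pars[["shape2"]])
  expect_equal(m, 0.85, tolerance = 1e-9)
  expect_lt(abs(qbeta(0.025, s$pars[["shape1"]], s$pars[["shape2"]]) - 0.40),
            0.15)
  set.seed(1)
  x <- sample_distribution(s, 2000)
  expect_true(all(x >= 0 & x <= 1))
  expect_equal(mean(x), 0.85, tolerance = 0.02)

  # cost: gamma, nonnegative, mean at base
  s <- fit_distribution("cost_resection", 29580, 15000, 41000)
  expect_equal(s$family, "gamma")
  x <- sample_distribution(s, 2000)
  expect_true(all(x >= 0))
  expect_equal(mean(x), 29580, tolerance = 0.05 * 29580)

  # disutility: beta on the magnitude, samples stay <= 0
  s <- fit_distribution("disutility_chemo", -0.12, -0.19, -0.05)
  expect_equal(s$family, "beta_neg")
  x <- sample_distribution(s, 2000)
  expect_true(all(x <= 0 & x >= -1))
  expect_equal(mean(x), -0.12, tolerance = 0.02)

  # degenerate range: point mass
  s <- fit_distribution("toxicity_rate", 0.5, 0.5, 0.5)
  expect_equal(s$family, "point")
  expect_equal(sample_distribution(s, 5), rep(0.5, 5))

  # infeasible beta (base at 0): uniform fallback, noted
  s <- fit_distribution("fistula_rate", 0, 0, 0.015)
  expect_equal(s$family, "uniform")
  expect_false(is.null(s$note))
  x <- sample_distribution(s, 500)
  expect_true(all(x >= 0 & x <= 0.015))

  expect_error(fit_distribution("x_rate", 0.2, 0.5, 0.6), "bracket")
})

test_that("every packaged parameter samples inside its natural bounds", {
  params <- load_parameters()
  specs <- build_psa_specs(params)
  set.seed(9)
  for (s in specs) {
    x <- sample_distribution(s, 200)
    if (grepl("^cost|^median", s$parameter)) {
      expect_true(all(x >= 0), label = s$parameter)
    } else if (grepl("^disutility", s$parameter)) {
      expect_true(all(x <= 0), label = s$parameter)
    } else if (!grepl("^start_age", s$parameter)) {
      expect_true(all(x >= 0 & x <= 1), label = s$parameter)
    }
  }
})

test_that("the tornado re-runs bounds with fixed calibration", {
  m <- base_model()
  tor <- one_way_dsa(m$params, m$calibration, m$life_table, wtp = 1e5)
  expect_false(any(tor$failed))
  # every ranged parameter appears at both bounds
  expect_equal(nrow(tor), nrow(attr(m$params$general, "ranges")) +
                 2 * nrow(attr(m$params$strategies$FOLFIRINOX, "ranges")))
  # sorted by span descending (NA last)
  sp <- tor$span[!is.na(tor$span)]
  expect_true(all(diff(sp) <= 1e-9))
  expect_equal(tor$span, abs(tor$icer_at_high - tor$icer_at_low),
               tolerance = 1e-9)

  # ICER is monotone in the strategy's own cost (QALYs unchanged)
  own_cost <- tor[tor$scope == "FOLFIRINOX" &
                    tor$parameter == "cost_chemo_cycle", ]
  expect_lt(own_cost$icer_at_low, own_cost$icer_at_high)

  # the recurrence-rate input is a calibration consistency check, not a
  # transition driver: zero span
  rec <- tor[tor$parameter == "recurrence_rate" &
               tor$scope == "FOLFIRINOX", ]
  expect_equal(rec$span, 0, tolerance = 1e-9)
})

test_that("the PSA is seed-reproducible and degenerate at point masses", {
  m <- base_model()
  p1 <- run_psa(m$params, m$calibration, m$life_table, n_iter = 30,
                seed = 11)
  p2 <- run_psa(m$params, m$calibration, m$life_table, n_iter = 30,
                seed = 11)
  expect_identical(p1$cost, p2$cost)
  expect_identical(p1$ceac, p2$ceac)
  expect_equal(length(p1$failed), 0)
  # CEAC shares sum to one at every WTP
  shares <- as.matrix(p1$ceac[, -1])
  expect_equal(unname(rowSums(shares)), rep(1, nrow(shares)),
               tolerance = 1e-12)

  point_specs <- build_psa_specs(m$params)
  point_specs <- lapply(point_specs, function(s) {
    p <- fit_distribution(s$parameter, s$base, s$base, s$base)
    p$scope <- s$scope
    p
  })
  p3 <- run_psa(m$params, m$calibration, m$life_table, n_iter = 3,
                seed = 2, specs = point_specs)
  base_cost <- vapply(m$outcomes, `[[`, 0, "total_cost")
  for (i in 1:3) {
    expect_equal(p3$cost[i, names(base_cost)], base_cost,
                 tolerance = 1e-9)
  }
  # all mass on the base-case optimum
  expect_equal(unname(p3$optimal_share["100000", "FOLFIRINOX"]), 1)
})

test_that("PSA means approach the base case as ranges shrink", {
  m <- base_model()
  shrink_specs <- function(f) {
    lapply(build_psa_specs(m$params), function(s) {
      p <- fit_distribution(s$parameter, s$base,
                            s$base - f * (s$base - s$low),
                            s$base + f * (s$high - s$base))
      p$scope <- s$scope
      p
    })
  }
  base_cost <- vapply(m$outcomes, `[[`, 0, "total_cost")
  err <- vapply(c(1, 0.2, 0.02), function(f) {
    p <- run_psa(m$params, m$calibration, m$life_table, n_iter = 120,
                 seed = 4, specs = shrink_specs(f))
    mean(abs(colMeans(p$cost[, names(base_cost)]) - base_cost))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("scenario overrides pass through, validate, and preserve the base", {
  m <- base_model()
  base_ce <- run_scenario(m$params, m$calibration, list(),
                          m$life_table)
  expect_equal(vapply(base_ce$outcomes, `[[`, 0, "total_cost"),
               vapply(m$outcomes, `[[`, 0, "total_cost"),
               tolerance = 1e-12)

  sc <- run_scenario(m$params, m$calibration,
                     list(name = "r0",
                          strategies = list(FOLFIRINOX =
                                              list(r0_rate = 0.88))),
                     m$life_table)
  expect_equal(as.numeric(sc$outcomes$FOLFIRINOX$r0_fraction), 0.88,
               tolerance = 1e-12)

  expect_error(run_scenario(m$params, m$calibration,
                            list(bogus_key = 1), m$life_table),
               "unknown scenario keys")
  expect_error(run_scenario(m$params, m$calibration,
                            list(strategies = list(FOLFIRINOX =
                                                     list(r0_rate = 1.4))),
                            m$life_table),
               class = "pdaccea_validation_error")

  ships <- read_scenario(system.file(
    "extdata", "scenario_center_of_excellence_synthetic.yaml",
    package = "pdaccea"))
  expect_equal(ships$strategies$FOLFIRINOX$r0_rate, 0.88)
})

test_that("raising survival anchors never lowers an arm's QALYs", {
  m <- base_model()
  base_q <- m$outcomes$FOLFIRINOX$qalys
  an <- read.csv(system.file("extdata", "survival_anchors.csv",
                             package = "pdaccea"), comment.char = "#")
  an <- an[an$arm == "FOLFIRINOX", ]
  better <- an
  better$survival <- ifelse(better$time_months == 0, 1,
                            pmin(1, better$survival + 0.05))
  sc <- run_scenario(m$params, m$calibration,
                     list(name = "better", anchors = better),
                     m$life_table, control = list(seed = 1, n_starts = 3))
  expect_gte(sc$outcomes$FOLFIRINOX$qalys, base_q - 1e-6)
})
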