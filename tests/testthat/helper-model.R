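# Shared fixtures: toy parameter constructors with analytically tractable
# hazards, and a memoized base-case calibration of the packaged model (the
# expensive step, computed once per test run).

toy_settings <- function(horizon = 24L, discount = 0,
                         split = c(second_line = 0.5, palliative = 0.3,
                                   death = 0.2)) {
  structure(list(
    horizon_cycles = as.integer(horizon), cycle_length_months = 1,
    discount_rate_annual = discount, wtp_primary = 1e5,
    wtp_thresholds = list(5e4, 1e5, 1.5e5), psa_iterations = 10L,
    rng_seed = 1L, dropout_split = as.list(split),
    chemoradiation_addon = TRUE, surgery_recovery_cycles = 1L
  ), class = "model_settings")
}

# flat life table: constant monthly background mortality at every age
flat_life_table <- function(monthly = 0) {
  q_annual <- 1 - (1 - monthly)^12
  lt <- data.frame(age = 30:90, annual_mortality = q_annual)
  lt$monthly_mortality <- 1 - (1 - lt$annual_mortality)^(1 / 12)
  lt
}

.with_ranges <- function(values, class) {
  ranged <- names(values)[vapply(values, is.numeric, TRUE)]
  ranged <- setdiff(ranged, c("n_cycles", "treated"))
  ranges <- data.frame(parameter = ranged,
                       base = unlist(values[ranged], use.names = FALSE),
                       low = unlist(values[ranged], use.names = FALSE),
                       high = unlist(values[ranged], use.names = FALSE))
  structure(values, ranges = ranges, class = class)
}

toy_general <- function(utility_pf = 0.8, utility_prog = 0.73,
                        utility_pall = 0.14, utility_recovery = 0.78,
                        surgical_mortality = 0, cost_eus = 0,
                        cost_inpatient = 0, cost_resection = 0,
                        cost_palliative = 0) {
  .with_ranges(list(
    start_age = 60, neoadjuvant_30day_mortality = 0.24,
    surgical_30day_mortality = surgical_mortality,
    postsurgical_fistula_rate = 0,
    utility_progression_free = utility_pf,
    utility_progressive = utility_prog,
    utility_palliative = utility_pall,
    utility_surgery_recovery = utility_recovery,
    cost_resection = cost_resection, cost_palliative_total = cost_palliative,
    cost_capecitabine_rt_month = 0, cost_chemoradiation_hosp = 0,
    cost_eus = cost_eus, cost_pdac_month_inpatient = cost_inpatient
  ), "general_params")
}

toy_treated <- function(name = "TOY", dropout = 0, toxicity = 0,
                        tox_hosp = 0, r0 = 0.85, cost_chemo = 0,
                        cost_tox = 0, cost_admin = 0, cost_sl = 0,
                        cost_sl_tox = 0, disutil_chemo = 0,
                        disutil_tox = 0) {
  .with_ranges(list(
    name = name, n_cycles = 6L, cycle_days = "toy", treated = TRUE,
    dropout_rate = dropout, toxicity_rate = toxicity,
    hospitalization_for_toxicity = tox_hosp,
    surgical_complication_rate = 0, fistula_rate = 0, r0_rate = r0,
    recurrence_rate = 0.5, lymph_node_positivity = 0.5,
    median_surv_recurrence_r0 = 21, median_surv_recurrence_r1 = 17,
    median_surv_recurrence_n0 = 22, median_surv_recurrence_n1 = 18,
    median_surv_second_line = 9,
    cost_chemo_cycle = cost_chemo, cost_toxicity_cycle = cost_tox,
    cost_second_line_month = cost_sl,
    cost_toxicity_second_line_month = cost_sl_tox,
    cost_admin_month = cost_admin,
    disutility_chemo = disutil_chemo, disutility_toxicity = disutil_tox
  ), "strategy_params")
}

toy_untreated <- function(name = "natural history") {
  .with_ranges(list(name = name, n_cycles = 0L, cycle_days = "none",
                    treated = FALSE), "strategy_params")
}

toy_hazards <- function(arm = "TOY", progression = 0, neo_death = 0,
                        rec_death = 0, sl_death = 0, pall_death = 0,
                        target = "RECURRENCE") {
  hazard_params(arm, piecewise_hazard(c(0, 144), progression),
                neoadjuvant_death = neo_death, recurrence_death = rec_death,
                second_line_death = sl_death, palliative_death = pall_death,
                progression_target = target)
}

# Base-case calibration of the packaged model, computed once and reused by
# calibration, sensitivity and acceptance tests.
base_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      params <- load_parameters()
      life_table <- load_life_table()
      calibration <- calibrate_model(params, life_table,
                                     control = list(seed = 1))
      hazards <- lapply(calibration, `[[`, "fitted")
      ev <- evaluate_strategies(params, hazards, life_table)
      cache <<- list(params = params, life_table = life_table,
                     calibration = calibration, hazards = hazards,
                     outcomes = ev$outcomes, ce = ev$ce)
    }
    cache
  }
})

# published survival summaries the calibration is checked against
published_endpoints <- list(
  FOLFIRINOX = list(median_os = 34.01, median_pfs = 29.54,
                    os_5y = 0.2938, os_10y = 0.0973,
                    pfs_5y = 0.2568, pfs_10y = 0.0848),
  `G-nP` = list(median_os = 28.27, median_pfs = 24.88,
                os_5y = 0.2133, os_10y = 0.0524,
                pfs_5y = 0.1792, pfs_10y = 0.0438),
  `natural history` = list(median_os = 13, median_pfs = 7.87,
                           os_5y = 0.002, os_10y = 1e-4,
                           pfs_5y = 1e-4, pfs_10y = 1e-4)
)
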