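# Monthly-cycle Markov cohort engine over the treatment-pathway health
# states. Time-inhomogeneity enters through age-dependent background
# mortality, the neoadjuvant/resection phase structure, and piecewise-
# constant calibrated progression hazards.

#' Health states of the cohort model
#'
#' NEOADJUVANT holds patients on first-line chemotherapy (and, in the
#' untreated comparator, is unused); RESECTION is a single-cycle transitional
#' state; REMISSION_R0/R1 hold resected patients by margin status;
#' RECURRENCE, SECOND_LINE and PALLIATIVE are progressive-disease states;
#' DEAD is absorbing.
#' @export
health_states <- function() {
  c("NEOADJUVANT", "RESECTION", "REMISSION_R0", "REMISSION_R1",
    "RECURRENCE", "SECOND_LINE", "PALLIATIVE", "DEAD")
}

.S <- function(name) match(name, health_states())

#' Per-arm calibrated transition probabilities
#'
#' Bundles the monthly transition probabilities that drive one arm's cohort:
#' the piecewise-constant progression hazard out of the progression-free
#' states, an additional neoadjuvant-phase death probability, and constant
#' monthly death probabilities for the progressive-disease states.
#' Post-recurrence mortality is the printed-median blend (R- and N-stratified)
#' scaled by a calibration multiplier.
#'
#' @param arm Arm label.
#' @param progression \code{\link{piecewise_hazard}} for the progression-free
#'   to progressed transition.
#' @param neoadjuvant_death Extra monthly death probability while on
#'   neoadjuvant therapy (0 for the untreated arm).
#' @param recurrence_death Monthly death probability in RECURRENCE.
#' @param second_line_death Monthly death probability in SECOND_LINE.
#' @param palliative_death Monthly death probability in PALLIATIVE.
#' @param progression_target State progressed patients enter:
#'   \code{"RECURRENCE"} (resected arms) or \code{"PALLIATIVE"} (untreated).
#' @param recurrence_mort_multiplier The calibration multiplier already
#'   folded into \code{recurrence_death}, kept for re-derivation when
#'   recurrence-survival medians are varied in sensitivity analyses.
#' @return Object of class \code{hazard_params}.
#' @export
hazard_params <- function(arm, progression, neoadjuvant_death = 0,
                          recurrence_death = 0, second_line_death = 0,
                          palliative_death = 0,
                          progression_target = "RECURRENCE",
                          recurrence_mort_multiplier = 1) {
  probs <- c(neoadjuvant_death, recurrence_death, second_line_death,
             palliative_death)
  if (any(probs < 0 | probs > 1)) {
    stop("monthly probabilities must lie in [0, 1]")
  }
  if (!progression_target %in% c("RECURRENCE", "PALLIATIVE")) {
    stop("progression_target must be RECURRENCE or PALLIATIVE")
  }
  structure(list(arm = arm, progression = progression,
                 neoadjuvant_death = neoadjuvant_death,
                 recurrence_death = recurrence_death,
                 second_line_death = second_line_death,
                 palliative_death = palliative_death,
                 progression_target = progression_target,
                 recurrence_mort_multiplier = recurrence_mort_multiplier),
            class = "hazard_params")
}

#' Blended monthly post-recurrence mortality from printed medians
#'
#' Joint R-by-N survival medians are not published, so the monthly
#' probability is the average of the R-stratified blend (weights
#' \code{r0_rate}, \code{1 - r0_rate}) and the N-stratified blend (weights
#' \code{1 - lymph_node_positivity}, \code{lymph_node_positivity}), each
#' converted from its median via the exponential assumption.
#'
#' @param strategy A treated \code{strategy_params}.
#' @return Monthly death probability in RECURRENCE (before any calibration
#'   multiplier).
#' @export
blended_recurrence_mortality <- function(strategy) {
  p <- function(m) median_to_monthly_prob(m)
  r_blend <- strategy$r0_rate * p(strategy$median_surv_recurrence_r0) +
    (1 - strategy$r0_rate) * p(strategy$median_surv_recurrence_r1)
  n_blend <- (1 - strategy$lymph_node_positivity) *
    p(strategy$median_surv_recurrence_n0) +
    strategy$lymph_node_positivity * p(strategy$median_surv_recurrence_n1)
  (r_blend + n_blend) / 2
}

#' Single-cycle transition matrix for one arm
#'
#' Competing risks within a cycle follow the death-first convention:
#' all-cause (and state-specific) death is evaluated first, cancer events
#' apply to survivors. During the neoadjuvant phase the treated cohort
#' experiences per-cycle dropout (cumulative dropout converted by
#' \code{1 - (1 - d)^(1/n)}) split between second-line, palliative care and
#' death; at the resection cycle the surviving mass passes through RESECTION
#' with 30-day surgical mortality and splits R0:R1.
#'
#' @param strategy \code{strategy_params} for the arm.
#' @param general \code{general_params}.
#' @param hazards \code{hazard_params} for the arm.
#' @param cycle 0-based cycle index (transition from \code{cycle} to
#'   \code{cycle + 1}).
#' @param settings \code{model_settings}.
#' @param bg Monthly background mortality at each cycle (vector from
#'   \code{\link{background_mortality}}).
#' @return 8 x 8 row-stochastic matrix over \code{\link{health_states}}.
#' @export
transition_matrix <- function(strategy, general, hazards, cycle, settings,
                              bg) {
  if (cycle >= settings$horizon_cycles) stop("cycle beyond horizon")
  states <- health_states()
  n <- length(states)
  M <- matrix(0, n, n, dimnames = list(states, states))
  q <- bg[cycle + 1L]

  stay_or_die <- function(extra) {
    # death-first: background, then the state's own hazard on survivors
    pd <- q + (1 - q) * extra
    c(die = pd, live = 1 - pd)
  }

  # progression-free (remission) rows
  pprog <- hazard_at(hazards$progression, cycle)
  tgt <- .S(hazards$progression_target)
  for (s in c(.S("REMISSION_R0"), .S("REMISSION_R1"))) {
    M[s, .S("DEAD")] <- q
    M[s, tgt] <- (1 - q) * pprog
    M[s, s] <- (1 - q) * (1 - pprog)
  }

  # neoadjuvant phase and resection (treated arms only)
  if (strategy$treated && strategy$n_cycles > 0) {
    nc <- strategy$n_cycles
    if (cycle < nc) {
      sd0 <- stay_or_die(hazards$neoadjuvant_death)
      pd_cycle <- 1 - (1 - strategy$dropout_rate)^(1 / nc)
      split <- unlist(settings$dropout_split)
      cont <- sd0[["live"]] * (1 - pd_cycle)
      drop <- sd0[["live"]] * pd_cycle
      M[.S("NEOADJUVANT"), ] <- 0
      M[.S("NEOADJUVANT"), .S("DEAD")] <- sd0[["die"]] +
        drop * split[["death"]]
      M[.S("NEOADJUVANT"), .S("SECOND_LINE")] <- drop * split[["second_line"]]
      M[.S("NEOADJUVANT"), .S("PALLIATIVE")] <- drop * split[["palliative"]]
      dest <- if (cycle == nc - 1L) .S("RESECTION") else .S("NEOADJUVANT")
      M[.S("NEOADJUVANT"), dest] <- M[.S("NEOADJUVANT"), dest] + cont
    } else {
      M[.S("NEOADJUVANT"), .S("DEAD")] <- q
      M[.S("NEOADJUVANT"), .S("NEOADJUVANT")] <- 1 - q
    }
    if (cycle == nc) {
      sdr <- stay_or_die(general$surgical_30day_mortality)
      M[.S("RESECTION"), .S("DEAD")] <- sdr[["die"]]
      M[.S("RESECTION"), .S("REMISSION_R0")] <- sdr[["live"]] *
        strategy$r0_rate
      M[.S("RESECTION"), .S("REMISSION_R1")] <- sdr[["live"]] *
        (1 - strategy$r0_rate)
    } else {
      M[.S("RESECTION"), .S("DEAD")] <- q
      M[.S("RESECTION"), .S("RESECTION")] <- 1 - q
    }
  } else {
    for (s in c(.S("NEOADJUVANT"), .S("RESECTION"))) {
      M[s, .S("DEAD")] <- q
      M[s, s] <- 1 - q
    }
  }

  for (spec in list(c("RECURRENCE", "recurrence_death"),
                    c("SECOND_LINE", "second_line_death"),
                    c("PALLIATIVE", "palliative_death"))) {
    s <- .S(spec[1])
    sd <- stay_or_die(hazards[[spec[2]]])
    M[s, .S("DEAD")] <- sd[["die"]]
    M[s, s] <- sd[["live"]]
  }

  M[.S("DEAD"), .S("DEAD")] <- 1

  if (any(M < -1e-12 | M > 1 + 1e-12)) {
    stop("transition probability outside [0, 1]: inconsistent parameters")
  }
  bad <- abs(rowSums(M) - 1) > 1e-9
  if (any(bad)) stop("transition rows do not sum to 1: ",
                     paste(states[bad], collapse = ", "))
  M
}

#' Run a cohort through a sequence of transition matrices
#'
#' The elementary matrix-vector recursion, exposed so that small analytic
#' chains can be checked against matrix-power solutions.
#'
#' @param init Initial occupancy vector (sums to 1).
#' @param matrices List of row-stochastic matrices, one per cycle.
#' @return Occupancy matrix with \code{length(matrices) + 1} rows.
#' @export
markov_trace <- function(init, matrices) {
  n <- length(matrices)
  occ <- matrix(0, n + 1L, length(init))
  occ[1L, ] <- init
  v <- init
  for (t in seq_len(n)) {
    v <- as.numeric(v %*% matrices[[t]])
    occ[t + 1L, ] <- v
  }
  colnames(occ) <- names(init) %||% colnames(matrices[[1]])
  occ
}

#' Run one arm's cohort over the full horizon
#'
#' The treated cohort starts 100\% in NEOADJUVANT; the untreated comparator
#' starts 100\% progression-free. Transition matrices are rebuilt only when
#' the phase, background-mortality age band or progression segment changes.
#'
#' @param strategy,general,hazards,settings Model inputs (see
#'   \code{\link{transition_matrix}}).
#' @param life_table Output of \code{\link{load_life_table}}.
#' @param store_flows Record per-cycle transition mass (needed for resection
#'   accounting; skipped in bulk probabilistic reruns for speed).
#' @return Object of class \code{cohort_trace}: list with \code{occupancy}
#'   (\code{horizon + 1} rows, one column per state), \code{flows}
#'   (cycle x from x to array or NULL), \code{arm} and \code{resection_cycle}
#'   (NA for the untreated arm).
#' @export
run_cohort <- function(strategy, general, hazards, settings, life_table,
                       store_flows = TRUE) {
  states <- health_states()
  horizon <- settings$horizon_cycles
  bg <- background_mortality(life_table, general$start_age, horizon)
  pprog <- hazard_at(hazards$progression, 0:(horizon - 1L))

  phase <- rep("post", horizon)
  nc <- if (strategy$treated) strategy$n_cycles else 0L
  if (nc > 0) {
    idx <- seq_len(min(nc, horizon))
    phase[idx] <- paste0("neo", idx - 1L)
    if (nc + 1L <= horizon) phase[nc + 1L] <- "resect"
  }
  key <- paste(phase, bg, pprog)
  mats <- vector("list", horizon)
  cache <- new.env(parent = emptyenv())
  for (t in seq_len(horizon)) {
    k <- key[t]
    if (is.null(cache[[k]])) {
      cache[[k]] <- transition_matrix(strategy, general, hazards, t - 1L,
                                      settings, bg)
    }
    mats[[t]] <- cache[[k]]
  }

  init <- setNames(numeric(length(states)), states)
  init[if (nc > 0) "NEOADJUVANT" else "REMISSION_R0"] <- 1
  occ <- markov_trace(init, mats)

  flows <- NULL
  if (store_flows) {
    flows <- array(0, dim = c(horizon, length(states), length(states)),
                   dimnames = list(NULL, states, states))
    for (t in seq_len(horizon)) flows[t, , ] <- occ[t, ] * mats[[t]]
  }
  structure(list(occupancy = occ, flows = flows, arm = strategy$name,
                 resection_cycle = if (nc > 0 && nc <= horizon) {
                   nc
                 } else {
                   NA_integer_
                 }),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  dead <- x$occupancy[nrow(x$occupancy), "DEAD"]
  cat(sprintf("<cohort_trace> %s: %d cycles, %.1f%% dead at horizon\n",
              x$arm, nrow(x$occupancy) - 1L, 100 * dead))
  invisible(x)
}

#' Overall or progression-free survival curve of a trace
#'
#' OS(t) is one minus the DEAD occupancy; PFS(t) is the mass neither dead
#' nor in a progressive-disease state (RECURRENCE, SECOND_LINE, PALLIATIVE).
#'
#' @param trace A \code{cohort_trace}.
#' @param endpoint \code{"OS"} or \code{"PFS"}.
#' @return Data frame with columns \code{month} and \code{survival}.
#' @export
survival_curve <- function(trace, endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  occ <- trace$occupancy
  s <- if (endpoint == "OS") {
    1 - occ[, "DEAD"]
  } else {
    occ[, "NEOADJUVANT"] + occ[, "RESECTION"] +
      occ[, "REMISSION_R0"] + occ[, "REMISSION_R1"]
  }
  data.frame(month = 0:(nrow(occ) - 1L), survival = unname(s))
}

#' Read a survival curve at arbitrary times
#'
#' Linear interpolation between the bracketing monthly points.
#'
#' @param curve Output of \code{\link{survival_curve}}.
#' @param times Months.
#' @return Survival probabilities.
#' @export
survival_at <- function(curve, times) {
  approx(curve$month, curve$survival, xout = times, rule = 2)$y
}

#' Median of a monthly survival curve
#'
#' Linear interpolation between the bracketing monthly points (the reading
#' consistent with mid-cycle event placement); if the curve never reaches
#' 0.5 within the horizon the result is \code{NA} with attribute
#' \code{censored = TRUE}.
#'
#' @param curve Output of \code{\link{survival_curve}}.
#' @return Median in months, or censored \code{NA}.
#' @export
median_survival <- function(curve) {
  below <- which(curve$survival <= 0.5)
  if (length(below) == 0) {
    return(structure(NA_real_, censored = TRUE))
  }
  i <- below[1]
  if (curve$survival[i] == 0.5) return(curve$month[i])
  s1 <- curve$survival[i - 1]
  s2 <- curve$survival[i]
  curve$month[i - 1] + (s1 - 0.5) / (s1 - s2) *
    (curve$month[i] - curve$month[i - 1])
}

#' Fraction of the cohort reaching resection
#'
#' Mass entering the RESECTION state divided by the initial cohort; the
#' untreated comparator has no resection cycle and returns \code{NA} with
#' attribute \code{undefined = TRUE}.
#'
#' @param trace A \code{cohort_trace}.
#' @return Proportion in [0, 1], or flagged \code{NA}.
#' @export
resection_rate <- function(trace) {
  if (is.na(trace$resection_cycle)) {
    return(structure(NA_real_, undefined = TRUE))
  }
  unname(trace$occupancy[trace$resection_cycle + 1L, "RESECTION"])
}

#' Fraction of resection survivors assigned R0 status
#'
#' Mass flowing RESECTION to REMISSION_R0 divided by all mass surviving the
#' resection cycle (RESECTION to either remission state). Requires flows to
#' have been stored; returns flagged \code{NA} when no mass was resected.
#'
#' @param trace A \code{cohort_trace} with flows.
#' @return Proportion in [0, 1], or flagged \code{NA}.
#' @export
r0_fraction <- function(trace) {
  if (is.na(trace$resection_cycle) || is.null(trace$flows) ||
      trace$resection_cycle + 1L > dim(trace$flows)[1]) {
    return(structure(NA_real_, undefined = TRUE))
  }
  fl <- trace$flows[trace$resection_cycle + 1L, "RESECTION", ]
  surv <- fl[["REMISSION_R0"]] + fl[["REMISSION_R1"]]
  if (surv <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  fl[["REMISSION_R0"]] / surv
}
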