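# Economic accrual: discounted costs and QALYs with half-cycle correction on
# QALYs and (undiscounted) life-years, and the ICER efficiency frontier.
# Payer perspective, no indirect costs; all inputs in 2021 USD.

#' Discount multiplier for a monthly cycle
#'
#' \code{(1 + annual_rate)^(-cycle / 12)}.
#'
#' @param cycle 0-based cycle index (months).
#' @param annual_rate Annual discount rate (e.g. 0.03).
#' @return Discount multiplier.
#' @examples
#' discount_factor(12, 0.03)  # 1 / 1.03
#' @export
discount_factor <- function(cycle, annual_rate) {
  if (any(cycle < 0)) stop("cycle must be >= 0")
  (1 + annual_rate)^(-cycle / 12)
}

#' Half-cycle-corrected occupancy of a trace
#'
#' Effective occupancy during cycle interval t is the mean of the start- and
#' end-of-cycle occupancy (transitions assumed mid-cycle on average).
#' Applied to QALY and life-year accrual only, not to costs.
#'
#' @param trace A \code{cohort_trace}.
#' @return Matrix with one row per cycle interval.
#' @export
half_cycle_occupancy <- function(trace) {
  occ <- trace$occupancy
  n <- nrow(occ)
  (occ[-n, , drop = FALSE] + occ[-1, , drop = FALSE]) / 2
}

# State utilities for one arm; errors (not clamps) on a negative computed
# utility, which signals a bad disutility input.
.state_utilities <- function(strategy, general) {
  u <- setNames(numeric(length(health_states())), health_states())
  u["NEOADJUVANT"] <- general$utility_progression_free
  if (strategy$treated) {
    u["NEOADJUVANT"] <- u["NEOADJUVANT"] + strategy$disutility_chemo +
      strategy$toxicity_rate * strategy$disutility_toxicity
  }
  u["RESECTION"] <- general$utility_surgery_recovery
  u["REMISSION_R0"] <- u["REMISSION_R1"] <- general$utility_progression_free
  u["RECURRENCE"] <- u["SECOND_LINE"] <- general$utility_progressive
  u["PALLIATIVE"] <- general$utility_palliative
  u["DEAD"] <- 0
  if (any(u < 0)) {
    stop("negative computed state utility (check disutility inputs): ",
         paste(names(u)[u < 0], collapse = ", "))
  }
  u
}

#' Accrue discounted costs, QALYs and clinical endpoints for one arm
#'
#' Cost accrual per cycle is the state-occupancy-weighted sum of:
#' chemotherapy + expected (rate-weighted) toxicity + administration during
#' the neoadjuvant phase, with the per-protocol capecitabine/radiation and
#' toxicity-hospitalization add-on in the final two neoadjuvant cycles;
#' resection plus complication/fistula hospitalization (one inpatient month
#' each) at the resection cycle; monthly inpatient disease-management cost
#' in recurrence; second-line drug + expected toxicity + administration in
#' SECOND_LINE; and the palliative total amortized over the expected
#' palliative sojourn. The untreated arm accrues the monthly inpatient cost
#' while progression-free and the palliative stream after progression; every
#' arm pays the endoscopic-ultrasound work-up at entry. QALYs use
#' half-cycle-corrected occupancy times state utilities; costs and QALYs are
#' discounted, life-years are half-cycle corrected but undiscounted.
#'
#' @param trace \code{cohort_trace} for the arm (with flows).
#' @param strategy,general,settings Model inputs.
#' @param hazards The arm's \code{hazard_params} (palliative amortization).
#' @return Object of class \code{econ_outcome}.
#' @export
accumulate_outcomes <- function(trace, strategy, general, settings, hazards) {
  occ <- trace$occupancy
  horizon <- nrow(occ) - 1L
  h <- half_cycle_occupancy(trace)
  u <- .state_utilities(strategy, general)
  df <- discount_factor(0:(horizon - 1L), settings$discount_rate_annual)
  nc <- if (strategy$treated) strategy$n_cycles else 0L

  pall_monthly <- general$cost_palliative_total * hazards$palliative_death
  cost <- numeric(horizon)
  trae <- numeric(horizon)
  for (t in 0:(horizon - 1L)) {
    o <- occ[t + 1L, ]
    ct <- 0
    if (t == 0) ct <- ct + general$cost_eus * (1 - o[["DEAD"]])
    if (strategy$treated) {
      if (t < nc) {
        tox <- strategy$toxicity_rate * strategy$cost_toxicity_cycle
        ct <- ct + o[["NEOADJUVANT"]] *
          (strategy$cost_chemo_cycle + tox + strategy$cost_admin_month)
        trae[t + 1L] <- trae[t + 1L] + o[["NEOADJUVANT"]] * tox
        if (isTRUE(settings$chemoradiation_addon) && t >= nc - 2L) {
          hosp <- strategy$hospitalization_for_toxicity *
            general$cost_chemoradiation_hosp
          ct <- ct + o[["NEOADJUVANT"]] *
            (general$cost_capecitabine_rt_month + hosp)
          trae[t + 1L] <- trae[t + 1L] + o[["NEOADJUVANT"]] * hosp
        }
      }
      if (t == nc) {
        ct <- ct + o[["RESECTION"]] *
          (general$cost_resection +
             (strategy$surgical_complication_rate + strategy$fistula_rate) *
               general$cost_pdac_month_inpatient)
      }
      sl_tox <- strategy$toxicity_rate * strategy$cost_toxicity_second_line_month
      ct <- ct + o[["SECOND_LINE"]] *
        (strategy$cost_second_line_month + sl_tox + strategy$cost_admin_month)
      trae[t + 1L] <- trae[t + 1L] + o[["SECOND_LINE"]] * sl_tox
      ct <- ct + o[["RECURRENCE"]] * general$cost_pdac_month_inpatient
    } else {
      ct <- ct + (o[["REMISSION_R0"]] + o[["REMISSION_R1"]]) *
        general$cost_pdac_month_inpatient
    }
    ct <- ct + o[["PALLIATIVE"]] * pall_monthly
    cost[t + 1L] <- ct
  }

  alive <- setdiff(health_states(), "DEAD")
  qaly_t <- as.numeric(h %*% u) / 12
  ly_t <- rowSums(h[, alive, drop = FALSE]) / 12

  os <- survival_curve(trace, "OS")
  pfs <- survival_curve(trace, "PFS")
  structure(list(
    strategy = strategy$name,
    total_cost = sum(cost * df),
    qalys = sum(qaly_t * df),
    life_years = sum(ly_t),
    median_os = median_survival(os),
    median_pfs = median_survival(pfs),
    landmark_os_5y = survival_at(os, 60),
    landmark_os_10y = survival_at(os, 120),
    landmark_pfs_5y = survival_at(pfs, 60),
    landmark_pfs_10y = survival_at(pfs, 120),
    trae_cost_month = if (any(trae > 1e-12)) {
      sum(trae) / sum(trae > 1e-12)
    } else {
      NA_real_
    },
    resection_rate = resection_rate(trace),
    r0_fraction = r0_fraction(trace)
  ), class = "econ_outcome")
}

#' @export
print.econ_outcome <- function(x, ...) {
  cat(sprintf(
    "<econ_outcome> %s: cost $%s, %.3f QALYs, %.2f LY, median OS %.2f mo\n",
    x$strategy, format(round(x$total_cost), big.mark = ","), x$qalys,
    x$life_years, x$median_os))
  invisible(x)
}

#' @export
as.data.frame.econ_outcome <- function(x, ...) {
  data.frame(lapply(unclass(x), function(v) {
    attributes(v) <- NULL
    if (is.null(v)) NA else v
  }), stringsAsFactors = FALSE)
}

#' Bind several outcomes into a summary table
#'
#' @param outcomes List of \code{econ_outcome}.
#' @return Data frame, one row per strategy.
#' @export
outcomes_table <- function(outcomes) {
  do.call(rbind, lapply(outcomes, as.data.frame))
}

#' Efficiency frontier and incremental cost-effectiveness ratios
#'
#' Strategies are sorted by cost; strictly dominated strategies (at least as
#' costly and no more effective than another, with one inequality strict)
#' are removed, then extended dominance (non-monotone ICER chain) is removed
#' iteratively. ICERs are computed pairwise along the remaining chain, and
#' the optimal strategy at each willingness-to-pay threshold is the highest-
#' QALY strategy whose frontier ICER does not exceed the threshold. Exact
#' cost/QALY ties are flagged and broken deterministically by label order.
#'
#' @param outcomes List of \code{econ_outcome} (or a data frame with columns
#'   \code{strategy}, \code{total_cost}, \code{qalys}).
#' @param wtp Willingness-to-pay threshold(s), USD per QALY.
#' @return Object of class \code{ce_result}: list with \code{outcomes}
#'   (cost-ordered data frame), \code{dominated}, \code{extended_dominated},
#'   \code{frontier} (data frame with \code{icer}), \code{optimal} (named by
#'   threshold) and \code{tie} flag.
#' @examples
#' # printed base-case triples: ICER of the top arm vs the middle arm is
#' # 35716 / 0.45 = 79368.9 on the rounded published values
#' @export
efficiency_frontier <- function(outcomes, wtp = 1e5) {
  df <- if (is.data.frame(outcomes)) {
    outcomes
  } else {
    do.call(rbind, lapply(outcomes, function(o) {
      data.frame(strategy = o$strategy, total_cost = o$total_cost,
                 qalys = o$qalys, stringsAsFactors = FALSE)
    }))
  }
  if (nrow(df) < 1) stop("need at least one strategy")
  df <- df[order(df$total_cost, -df$qalys, df$strategy), , drop = FALSE]
  rownames(df) <- NULL

  tie <- any(duplicated(df[, c("total_cost", "qalys")]))

  dominated <- character()
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j) next
      ci <- df$total_cost[i]; cj <- df$total_cost[j]
      qi <- df$qalys[i]; qj <- df$qalys[j]
      strictly <- (cj <= ci && qj >= qi) && (cj < ci || qj > qi)
      if (strictly) dominated <- union(dominated, df$strategy[i])
    }
  }
  front <- df[!df$strategy %in% dominated, , drop = FALSE]

  extended <- character()
  repeat {
    if (nrow(front) < 3) break
    icers <- c(NA, diff(front$total_cost) / diff(front$qalys))
    drop_idx <- NULL
    for (i in 2:(nrow(front) - 1)) {
      if (!is.na(icers[i]) && !is.na(icers[i + 1]) &&
          icers[i] > icers[i + 1]) {
        drop_idx <- i
        break
      }
    }
    if (is.null(drop_idx)) break
    extended <- union(extended, front$strategy[drop_idx])
    front <- front[-drop_idx, , drop = FALSE]
  }

  front$icer <- c(NA, diff(front$total_cost) / diff(front$qalys))

  optimal <- vapply(wtp, function(w) {
    ok <- which(is.na(front$icer) | front$icer <= w)
    # frontier ICERs increase, so affordable strategies are a prefix chain
    front$strategy[max(ok)]
  }, character(1))
  names(optimal) <- format(wtp, scientific = FALSE, trim = TRUE)

  structure(list(outcomes = df, dominated = dominated,
                 extended_dominated = extended, frontier = front,
                 optimal = optimal, wtp = wtp, tie = tie),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result> frontier:\n")
  print(x$frontier, row.names = FALSE, digits = 6)
  if (length(x$dominated)) {
    cat("dominated:", paste(x$dominated, collapse = ", "), "\n")
  }
  if (length(x$extended_dominated)) {
    cat("extended dominated:", paste(x$extended_dominated, collapse = ", "),
        "\n")
  }
  for (i in seq_along(x$optimal)) {
    cat(sprintf("optimal at WTP $%s: %s\n", names(x$optimal)[i],
                x$optimal[i]))
  }
  invisible(x)
}

#' Frontier ICER of a named strategy
#'
#' Convenience accessor for sensitivity analyses: returns the strategy's
#' ICER versus the next-cheaper non-dominated strategy, \code{Inf} if the
#' strategy was (extended-)dominated, and \code{NA} if it is the cheapest
#' frontier strategy.
#'
#' @param ce A \code{ce_result}.
#' @param strategy Strategy label.
#' @return ICER in USD/QALY, \code{Inf}, or \code{NA}.
#' @export
frontier_icer <- function(ce, strategy) {
  if (strategy %in% c(ce$dominated, ce$extended_dominated)) {
    return(Inf)
  }
  i <- match(strategy, ce$frontier$strategy)
  if (is.na(i)) stop("unknown strategy '", strategy, "'")
  ce$frontier$icer[i]
}
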