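# Survival anchors and piecewise-constant hazard fixtures. Anchors are the
# published per-arm survival summaries (median, 5-year and 10-year OS/PFS);
# the synthetic generator produces anchors from known hazards so that the
# calibration can be tested by parameter recovery.

.known_arms <- c("FOLFIRINOX", "G-nP", "natural history")

#' Construct a survival anchor set for one arm and endpoint
#'
#' Anchors are \code{(0, 1)}, \code{(median, 0.5)}, \code{(60, 5-year)} and
#' \code{(120, 10-year)}, read from the packaged transcription of the
#' published survival summaries. Zero long-term survival in the
#' natural-history arm is encoded as 1e-4 to keep fitted hazards finite.
#'
#' @param arm One of \code{"FOLFIRINOX"}, \code{"G-nP"},
#'   \code{"natural history"}.
#' @param endpoint \code{"OS"} or \code{"PFS"}.
#' @param path CSV of anchor rows (\code{arm, endpoint, time_months,
#'   survival}); defaults to the packaged fixture.
#' @return Object of class \code{survival_anchors}: list with \code{arm},
#'   \code{endpoint} and a data frame \code{anchors} with columns
#'   \code{time} and \code{survival}.
#' @examples
#' a <- build_anchor_set("FOLFIRINOX", "OS")
#' a$anchors  # contains (34.01, 0.5) and (120, 0.0973)
#' @export
build_anchor_set <- function(arm, endpoint,
                             path = system.file("extdata",
                                                "survival_anchors.csv",
                                                package = "pdaccea")) {
  if (!arm %in% .known_arms) {
    stop("unknown arm '", arm, "'; expected one of: ",
         paste(.known_arms, collapse = ", "))
  }
  if (!endpoint %in% c("OS", "PFS")) {
    stop("unknown endpoint '", endpoint, "'; expected OS or PFS")
  }
  tab <- read.csv(path, comment.char = "#")
  rows <- tab[tab$arm == arm & tab$endpoint == endpoint, ]
  if (nrow(rows) == 0) stop("no anchors for ", arm, "/", endpoint)
  anchors <- data.frame(time = rows$time_months, survival = rows$survival)
  anchors <- anchors[order(anchors$time), , drop = FALSE]
  rownames(anchors) <- NULL
  .validate_anchors(anchors)
  structure(list(arm = arm, endpoint = endpoint, anchors = anchors),
            class = "survival_anchors")
}

.validate_anchors <- function(anchors) {
  if (anchors$time[1] != 0 || anchors$survival[1] != 1) {
    stop("anchor set must start at (0, 1)")
  }
  if (is.unsorted(anchors$time, strictly = TRUE)) {
    stop("anchor times must be strictly increasing")
  }
  if (any(diff(anchors$survival) > 1e-12)) {
    stop("anchor survival must be non-increasing")
  }
  if (any(anchors$survival < 0 | anchors$survival > 1)) {
    stop("anchor survival must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Piecewise-constant hazard description
#'
#' @param breaks Increasing month boundaries; the k-th monthly probability
#'   applies to cycles in \code{[breaks[k], breaks[k+1])}.
#' @param probs Monthly event probabilities per segment,
#'   \code{length(breaks) - 1} of them.
#' @return Object of class \code{piecewise_hazard}.
#' @export
piecewise_hazard <- function(breaks, probs) {
  if (length(probs) != length(breaks) - 1) {
    stop("need one probability per segment (length(breaks) - 1)")
  }
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must increase")
  if (any(probs < 0 | probs > 1)) stop("monthly probabilities must be in [0, 1]")
  structure(list(breaks = breaks, probs = probs), class = "piecewise_hazard")
}

#' Monthly event probability of a piecewise hazard at given cycles
#'
#' Cycles at or beyond the last break keep the final segment's probability.
#'
#' @param hazard A \code{piecewise_hazard}.
#' @param cycles Integer cycle indices (months since model entry).
#' @return Numeric vector of monthly probabilities.
#' @export
hazard_at <- function(hazard, cycles) {
  idx <- findInterval(cycles, hazard$breaks, rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), length(hazard$probs))
  hazard$probs[idx]
}

#' Survival function implied by a piecewise-constant monthly hazard
#'
#' Survival at integer month t is the product of per-cycle survival
#' probabilities over cycles 0..t-1; non-integer times are linearly
#' interpolated between the bracketing months.
#'
#' @param hazard A \code{piecewise_hazard}.
#' @param times Non-negative times in months.
#' @return Survival probabilities at \code{times}.
#' @export
piecewise_survival <- function(hazard, times) {
  if (any(times < 0)) stop("times must be non-negative")
  tmax <- ceiling(max(times, 1))
  surv <- cumprod(c(1, 1 - hazard_at(hazard, 0:(tmax - 1))))
  approx(0:tmax, surv, xout = times)$y
}

#' Generate synthetic survival anchors from known hazards
#'
#' The parameter-recovery fixture: survival is computed exactly from the
#' piecewise-constant hazards, optionally perturbed by truncated zero-mean
#' Gaussian noise, and monotonicity is enforced after perturbation. The
#' result is deterministic given \code{seed}.
#'
#' @param hazard A \code{piecewise_hazard}.
#' @param times Sorted positive anchor times (months).
#' @param noise_sd Standard deviation of the perturbation (proportion scale);
#'   0 gives exact values.
#' @param seed Integer RNG seed (used only when \code{noise_sd > 0}).
#' @param arm,endpoint Labels stored on the result.
#' @return A \code{survival_anchors} object including the leading (0, 1)
#'   anchor.
#' @examples
#' h <- piecewise_hazard(c(0, 10), 0.5)
#' generate_synthetic_anchors(h, c(1, 2))$anchors  # (1, 0.5), (2, 0.25)
#' @export
generate_synthetic_anchors <- function(hazard, times, noise_sd = 0,
                                       seed = 1L, arm = "synthetic",
                                       endpoint = "OS") {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE)) {
    stop("times must be sorted and positive")
  }
  s <- piecewise_survival(hazard, times)
  if (noise_sd > 0) {
    set.seed(seed)
    s <- pmin(pmax(s + stats::rnorm(length(s), 0, noise_sd), 0), 1)
  }
  s <- cummin(c(1, s))  # enforce monotone non-increasing incl. S(0) = 1
  anchors <- data.frame(time = c(0, times), survival = s)
  structure(list(arm = arm, endpoint = endpoint, anchors = anchors),
            class = "survival_anchors")
}

#' @export
print.survival_anchors <- function(x, ...) {
  cat(sprintf("<survival_anchors> %s %s, %d points\n", x$arm, x$endpoint,
              nrow(x$anchors)))
  print(x$anchors, row.names = FALSE)
  invisible(x)
}

# ---- background (all-cause) mortality ---------------------------------------

#' Load the packaged abridged all-cause mortality table
#'
#' @param path CSV with columns \code{age, annual_mortality}; defaults to the
#'   packaged male/female-averaged 2016 U.S. period life table extract.
#' @return Data frame with an added \code{monthly_mortality} column
#'   (\code{1 - (1 - q)^(1/12)}).
#' @export
load_life_table <- function(path = system.file("extdata",
                                               "life_table_2016_us.csv",
                                               package = "pdaccea")) {
  lt <- read.csv(path, comment.char = "#")
  if (any(lt$annual_mortality < 0 | lt$annual_mortality > 1)) {
    stop("life table probabilities must be in [0, 1]")
  }
  lt$monthly_mortality <- 1 - (1 - lt$annual_mortality)^(1 / 12)
  lt
}

#' Monthly background mortality for each model cycle
#'
#' Age advances by one year every 12 cycles from the entry age (fractional
#' entry ages take the completed-year row); ages outside the table are
#' clamped to its ends.
#'
#' @param life_table Output of \code{\link{load_life_table}}.
#' @param start_age Age in years at model entry.
#' @param n_cycles Number of monthly cycles.
#' @return Numeric vector of length \code{n_cycles}: monthly all-cause death
#'   probability at each cycle.
#' @export
background_mortality <- function(life_table, start_age, n_cycles) {
  ages <- floor(start_age) + (seq_len(n_cycles) - 1L) %/% 12L
  ages <- pmin(pmax(ages, min(life_table$age)), max(life_table$age))
  life_table$monthly_mortality[match(ages, life_table$age)]
}
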