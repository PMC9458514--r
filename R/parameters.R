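# Parameter containers: general parameters (Table-1-style), strategy-specific
# parameters (Table-2-style) and run settings, each read from human-diffable
# YAML files so the transcription can be audited line by line.

# Fields of a strategy file that carry {value, low, high} entries.
.strategy_ranged_fields <- c(
  "dropout_rate", "toxicity_rate", "hospitalization_for_toxicity",
  "surgical_complication_rate", "fistula_rate", "r0_rate", "recurrence_rate",
  "lymph_node_positivity",
  "median_surv_recurrence_r0", "median_surv_recurrence_r1",
  "median_surv_recurrence_n0", "median_surv_recurrence_n1",
  "median_surv_second_line",
  "cost_chemo_cycle", "cost_toxicity_cycle", "cost_second_line_month",
  "cost_toxicity_second_line_month", "cost_admin_month",
  "disutility_chemo", "disutility_toxicity"
)

.general_ranged_fields <- c(
  "start_age", "neoadjuvant_30day_mortality", "surgical_30day_mortality",
  "postsurgical_fistula_rate", "utility_progression_free",
  "utility_progressive", "utility_palliative", "utility_surgery_recovery",
  "cost_resection", "cost_palliative_total", "cost_capecitabine_rt_month",
  "cost_chemoradiation_hosp", "cost_eus", "cost_pdac_month_inpatient"
)

validation_error <- function(field, msg) {
  stop(structure(
    class = c("pdaccea_validation_error", "error", "condition"),
    list(message = sprintf("parameter '%s': %s", field, msg),
         call = NULL, field = field)
  ))
}

.unpack_ranged <- function(raw, fields, label) {
  values <- list()
  ranges <- data.frame(parameter = character(), base = numeric(),
                       low = numeric(), high = numeric())
  for (f in fields) {
    if (is.null(raw[[f]])) {
      validation_error(f, sprintf("missing from %s", label))
    }
    entry <- raw[[f]]
    if (!is.list(entry) || is.null(entry$value) ||
        is.null(entry$low) || is.null(entry$high)) {
      validation_error(f, "must be a {value, low, high} mapping")
    }
    v <- as.numeric(entry$value)
    lo <- as.numeric(entry$low)
    hi <- as.numeric(entry$high)
    if (any(is.na(c(v, lo, hi)))) validation_error(f, "non-numeric entry")
    if (lo > v || v > hi) {
      validation_error(f, sprintf("range (%g, %g) does not bracket base %g",
                                  lo, hi, v))
    }
    values[[f]] <- v
    ranges <- rbind(ranges, data.frame(parameter = f, base = v,
                                       low = lo, high = hi))
  }
  list(values = values, ranges = ranges)
}

.check_bounds <- function(values, ranges) {
  prob_like <- grepl("rate|mortality|positivity|^utility", names(values)) &
    !grepl("^median|^cost|^start_age", names(values))
  for (f in names(values)[prob_like]) {
    lim <- ranges[ranges$parameter == f, ]
    if (values[[f]] < 0 || values[[f]] > 1 || lim$low < 0 || lim$high > 1) {
      validation_error(f, "probability/utility outside [0, 1]")
    }
  }
  for (f in grep("^cost", names(values), value = TRUE)) {
    lim <- ranges[ranges$parameter == f, ]
    if (values[[f]] < 0 || lim$low < 0) validation_error(f, "negative cost")
  }
  for (f in grep("^median", names(values), value = TRUE)) {
    if (values[[f]] <= 0) validation_error(f, "median must be positive")
  }
  for (f in grep("^disutility", names(values), value = TRUE)) {
    lim <- ranges[ranges$parameter == f, ]
    if (values[[f]] > 0 || lim$high > 0) {
      validation_error(f, "disutility must be <= 0")
    }
  }
  invisible(TRUE)
}

#' Read the general model parameters from a YAML file
#'
#' @param path Path to a general-parameters YAML file in which every entry is
#'   a \code{{value, low, high}} mapping.
#' @return An object of class \code{general_params}: a named list of base
#'   values with the sensitivity ranges attached as the \code{"ranges"}
#'   attribute (a data frame with columns \code{parameter}, \code{base},
#'   \code{low}, \code{high}).
#' @export
read_general_params <- function(path) {
  if (!file.exists(path)) validation_error("general", paste("no file", path))
  raw <- yaml::read_yaml(path)
  up <- .unpack_ranged(raw, .general_ranged_fields, basename(path))
  .check_bounds(up$values, up$ranges)
  structure(up$values, ranges = up$ranges, class = "general_params")
}

#' Read one strategy's parameters from a YAML file
#'
#' The natural-history comparator carries no chemotherapy fields; treatment
#' strategies must carry the full Table-2-style field set.
#'
#' @param path Path to a strategy YAML file.
#' @return An object of class \code{strategy_params}.
#' @export
read_strategy_params <- function(path) {
  if (!file.exists(path)) validation_error("strategy", paste("no file", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$name)) validation_error("name", "missing strategy name")
  treated <- !identical(raw$name, "natural history")
  base <- list(name = raw$name,
               n_cycles = as.integer(raw$n_cycles %||% 0L),
               cycle_days = raw$cycle_days %||% "none",
               treated = treated)
  if (!treated) {
    return(structure(base,
                     ranges = data.frame(parameter = character(),
                                         base = numeric(), low = numeric(),
                                         high = numeric()),
                     class = "strategy_params"))
  }
  up <- .unpack_ranged(raw, .strategy_ranged_fields, basename(path))
  .check_bounds(up$values, up$ranges)
  structure(c(base, up$values), ranges = up$ranges,
            class = "strategy_params")
}

#' Read the model run settings
#'
#' @param path Path to a settings YAML file.
#' @return An object of class \code{model_settings}.
#' @export
read_settings <- function(path) {
  if (!file.exists(path)) validation_error("settings", paste("no file", path))
  s <- yaml::read_yaml(path)
  s$horizon_cycles <- as.integer(s$horizon_cycles)
  if (is.null(s$horizon_cycles) || s$horizon_cycles <= 0) {
    validation_error("horizon_cycles", "must be a positive integer")
  }
  if (s$discount_rate_annual < 0 || s$discount_rate_annual >= 1) {
    validation_error("discount_rate_annual", "must be in [0, 1)")
  }
  split <- unlist(s$dropout_split)
  if (is.null(split) ||
      !setequal(names(split), c("second_line", "palliative", "death")) ||
      abs(sum(split) - 1) > 1e-9 || any(split < 0)) {
    validation_error("dropout_split",
                     "must name second_line/palliative/death and sum to 1")
  }
  structure(s, class = "model_settings")
}

#' Load the full packaged (or user-supplied) parameter set
#'
#' Reads \code{general.yaml}, \code{settings.yaml} and every
#' \code{strategy_*.yaml} from a directory, validating all invariants; any
#' violation is raised as a structured validation error naming the field.
#'
#' @param path Directory of parameter files. Defaults to the files shipped
#'   with the package, which transcribe the published parameter tables.
#' @return A list with elements \code{general} (\code{general_params}),
#'   \code{strategies} (named list of \code{strategy_params}, treatment arms
#'   first) and \code{settings} (\code{model_settings}).
#' @examples
#' params <- load_parameters()
#' params$strategies$FOLFIRINOX$r0_rate   # 0.85
#' @export
load_parameters <- function(path = system.file("extdata",
                                               package = "pdaccea")) {
  if (!dir.exists(path)) validation_error("path", paste("no directory", path))
  general <- read_general_params(file.path(path, "general.yaml"))
  settings <- read_settings(file.path(path, "settings.yaml"))
  files <- sort(list.files(path, pattern = "^strategy_.*\\.yaml$",
                           full.names = TRUE))
  if (length(files) == 0) validation_error("strategies", "no strategy files")
  strategies <- lapply(files, read_strategy_params)
  names(strategies) <- vapply(strategies, `[[`, "", "name")
  # deterministic order: treated arms alphabetically, then natural history
  treated <- vapply(strategies, `[[`, TRUE, "treated")
  strategies <- c(strategies[sort(names(strategies)[treated])],
                  strategies[!treated])
  list(general = general, strategies = strategies, settings = settings)
}

#' Write a parameter object back to YAML
#'
#' Inverse of the readers: \code{write_parameters} followed by the matching
#' reader reproduces the object (round-trip identity).
#'
#' @param params A \code{general_params} or \code{strategy_params} object.
#' @param path Output YAML path.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(params, path) {
  ranges <- attr(params, "ranges")
  out <- list()
  for (f in names(params)) {
    if (f %in% ranges$parameter) {
      r <- ranges[ranges$parameter == f, ]
      out[[f]] <- list(value = params[[f]], low = r$low, high = r$high)
    } else if (f != "treated") {
      out[[f]] <- params[[f]]
    }
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Look up a parameter's sensitivity range
#'
#' @param params Parameter object with a \code{"ranges"} attribute.
#' @param field Parameter name.
#' @return Named numeric vector \code{c(low, high)}.
#' @export
param_range <- function(params, field) {
  ranges <- attr(params, "ranges")
  r <- ranges[ranges$parameter == field, ]
  if (nrow(r) == 0) validation_error(field, "has no sensitivity range")
  c(low = r$low, high = r$high)
}

#' Replace a parameter value, keeping its range metadata
#'
#' Used by the sensitivity analyses; the replacement must satisfy the same
#' bounds as the base field.
#'
#' @param params Parameter object.
#' @param field Parameter name.
#' @param value New value.
#' @return The modified object.
#' @export
set_param <- function(params, field, value) {
  if (is.null(params[[field]])) validation_error(field, "unknown parameter")
  params[[field]] <- value
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.strategy_params <- function(x, ...) {
  cat(sprintf("<strategy_params> %s (%s)\n", x$name,
              if (x$treated) "treated arm" else "comparator"))
  if (x$treated) {
    cat(sprintf("  %d neoadjuvant cycles, dropout %.2f, R0 rate %.2f\n",
                x$n_cycles, x$dropout_rate, x$r0_rate))
  }
  invisible(x)
}

#' @export
print.general_params <- function(x, ...) {
  cat("<general_params>", length(unclass(x)), "fields\n")
  invisible(x)
}
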