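# End-to-end runs and run artifacts: calibrate -> cohort -> economics ->
# frontier for all arms, plus optional sensitivity stages, each writing
# plain-text outputs and a manifest.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Export a cohort trace as CSV
#'
#' Columns: cycle, one per state, OS and PFS.
#'
#' @param trace A \code{cohort_trace}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(cycle = 0:(nrow(trace$occupancy) - 1L), trace$occupancy,
                   OS = survival_curve(trace, "OS")$survival,
                   PFS = survival_curve(trace, "PFS")$survival)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full base-case analysis and write artifacts
#'
#' Executes calibrate -> cohort -> economics -> frontier for every strategy
#' and writes: a per-strategy summary table (costs, QALYs, survival
#' endpoints, ICERs), per-arm traces and survival curves, calibration
#' results (fitted parameters and residuals), frontier plot data, and a run
#' manifest listing every output. Optional stages add the tornado, the PSA
#' (draws + CEAC) and a scenario run.
#'
#' @param config_dir Directory of parameter YAML files (default: packaged).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving calibration multistarts and the PSA.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @param stages Character subset of \code{c("base", "dsa", "psa",
#'   "scenario")}.
#' @param psa_iterations PSA iteration count (default from settings).
#' @param scenario_file Scenario YAML (default: packaged synthetic
#'   center-of-excellence example).
#' @param verbose Print progress.
#' @return The run manifest (list), invisibly; all artifacts on disk.
#' @export
run_analysis <- function(config_dir = system.file("extdata",
                                                  package = "pdaccea"),
                         out_dir, seed = 1L, wtp = NULL, stages = "base",
                         psa_iterations = NULL, scenario_file = NULL,
                         verbose = TRUE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- load_parameters(config_dir)
  life_table <- load_life_table()
  wtp <- wtp %||% params$settings$wtp_primary
  outputs <- character()
  keep <- function(p) {
    outputs <<- c(outputs, p)
    p
  }

  say("calibrating ", length(params$strategies), " arms ...")
  calibration <- calibrate_model(params, life_table,
                                 control = list(seed = seed))
  for (nm in names(calibration)) {
    if (!calibration[[nm]]$converged) {
      warning("calibration did not converge for ", nm)
    }
  }
  cal_art <- lapply(calibration, function(cr) {
    list(par = cr$par, objective = cr$objective_value,
         converged = cr$converged)
  })
  .write_json(cal_art, keep(file.path(out_dir, "calibration.json")))
  write.csv(do.call(rbind, lapply(calibration, `[[`, "residuals")),
            keep(file.path(out_dir, "calibration_residuals.csv")),
            row.names = FALSE)

  say("running cohorts and economics ...")
  hazards <- lapply(calibration, `[[`, "fitted")
  ev <- evaluate_strategies(params, hazards, life_table, wtp = wtp)
  for (nm in names(params$strategies)) {
    hz <- update_hazards(hazards[[nm]], params$strategies[[nm]])
    trace <- run_cohort(params$strategies[[nm]], params$general, hz,
                        params$settings, life_table)
    slug <- gsub("[^A-Za-z0-9]+", "_", tolower(nm))
    write_trace_csv(trace, keep(file.path(out_dir,
                                          paste0("trace_", slug, ".csv"))))
  }

  summary_df <- outcomes_table(ev$outcomes)
  summary_df$icer <- vapply(summary_df$strategy,
                            function(s) frontier_icer(ev$ce, s), numeric(1))
  write.csv(summary_df, keep(file.path(out_dir, "summary.csv")),
            row.names = FALSE)
  write.csv(ev$ce$outcomes[, c("strategy", "total_cost", "qalys")],
            keep(file.path(out_dir, "frontier_points.csv")),
            row.names = FALSE)
  .write_json(list(frontier = ev$ce$frontier,
                   dominated = ev$ce$dominated,
                   extended_dominated = ev$ce$extended_dominated,
                   optimal = as.list(ev$ce$optimal)),
              keep(file.path(out_dir, "frontier.json")))

  if ("dsa" %in% stages) {
    say("one-way sensitivity analysis ...")
    tor <- one_way_dsa(params, calibration, life_table, wtp = wtp)
    write.csv(tor, keep(file.path(out_dir, "tornado.csv")),
              row.names = FALSE)
  }
  if ("psa" %in% stages) {
    n_iter <- psa_iterations %||% params$settings$psa_iterations
    say("probabilistic sensitivity analysis (", n_iter, " iterations) ...")
    psa <- run_psa(params, calibration, life_table, n_iter = n_iter,
                   seed = seed,
                   wtp_thresholds = unlist(params$settings$wtp_thresholds))
    draws <- data.frame(iteration = seq_len(nrow(psa$cost)),
                        cost = psa$cost, qalys = psa$qalys)
    write.csv(draws, keep(file.path(out_dir, "psa_draws.csv")),
              row.names = FALSE)
    write.csv(psa$ceac, keep(file.path(out_dir, "ceac.csv")),
              row.names = FALSE)
    .write_json(list(iterations = psa$iterations, failed = psa$failed,
                     optimal_share = as.data.frame(psa$optimal_share)),
                keep(file.path(out_dir, "psa_summary.json")))
  }
  if ("scenario" %in% stages) {
    scenario_file <- scenario_file %||%
      system.file("extdata", "scenario_center_of_excellence_synthetic.yaml",
                  package = "pdaccea")
    say("scenario run: ", scenario_file)
    sc <- run_scenario(params, calibration, read_scenario(scenario_file),
                       life_table, wtp = wtp,
                       control = list(seed = seed))
    sc_df <- outcomes_table(sc$outcomes)
    sc_df$icer <- vapply(sc_df$strategy,
                         function(s) frontier_icer(sc$ce, s), numeric(1))
    write.csv(sc_df, keep(file.path(out_dir,
                                    paste0("scenario_", sc$name, ".csv"))),
              row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(packageVersion("pdaccea")),
    config_dir = normalizePath(config_dir),
    seed = seed, wtp = wtp, stages = stages,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  missing <- outputs[!file.exists(outputs)]
  if (length(missing)) stop("missing outputs: ", paste(missing,
                                                       collapse = ", "))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  say("done in ", format(round(difftime(Sys.time(), t0, units = "secs"))),
      "; outputs in ", out_dir)
  invisible(manifest)
}
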