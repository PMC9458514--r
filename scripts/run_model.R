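#!/usr/bin/env Rscript
# Thin command-line wrapper over the package pipeline.
#
#   Rscript scripts/run_model.R [run|dsa|psa|scenario|all] \
#       [--config DIR] [--out DIR] [--seed N] [--wtp N] \
#       [--iterations N] [--scenario FILE]

suppressPackageStartupMessages({
  library(optparse)
  library(pdaccea)
})

parser <- OptionParser(
  usage = "%prog [run|dsa|psa|scenario|all] [options]",
  option_list = list(
    make_option("--config", type = "character",
                default = system.file("extdata", package = "pdaccea"),
                help = "directory of parameter YAML files"),
    make_option("--out", type = "character", default = "results",
                help = "output directory [default %default]"),
    make_option("--seed", type = "integer", default = 1L,
                help = "RNG seed [default %default]"),
    make_option("--wtp", type = "double", default = NA,
                help = "willingness-to-pay threshold, USD/QALY"),
    make_option("--iterations", type = "integer", default = NA,
                help = "PSA iterations (default: settings file)"),
    make_option("--scenario", type = "character", default = NULL,
                help = "scenario override YAML")
  ))
parsed <- parse_args(parser, positional_arguments = TRUE)
cmd <- if (length(parsed$args)) parsed$args[1] else "run"
opt <- parsed$options

stages <- switch(cmd,
  run = "base",
  dsa = c("base", "dsa"),
  psa = c("base", "psa"),
  scenario = c("base", "scenario"),
  all = c("base", "dsa", "psa", "scenario"),
  stop("unknown subcommand '", cmd,
       "'; expected run, dsa, psa, scenario or all"))

status <- tryCatch({
  run_analysis(config_dir = opt$config, out_dir = opt$out, seed = opt$seed,
               wtp = if (is.na(opt$wtp)) NULL else opt$wtp,
               stages = stages,
               psa_iterations = if (is.na(opt$iterations)) NULL else
                 opt$iterations,
               scenario_file = opt$scenario)
  0L
}, error = function(e) {
  message("ERROR: ", conditionMessage(e))
  1L
})
quit(status = status)
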