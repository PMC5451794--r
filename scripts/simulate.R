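#!/usr/bin/env Rscript
# Command-line front end for the boldsim simulator.
#
#   Rscript scripts/simulate.R run       [--config cfg.yaml] [--seed 1] [--out dir] [--prefix run]
#   Rscript scripts/simulate.R reference [--config cfg.yaml] [--seed 1] [--out dir] [--evolve]
#   Rscript scripts/simulate.R sweep     [--config cfg.yaml] [--seed 1] [--out dir]
#                                        [--lambdas 0.4,0.5,...] [--levels O1,O2,O3,O4]
#
# `run` plays a single evolution of the personality model, `reference` the
# model without personality traits, and `sweep` a replicate grid over update
# rates and difficulty levels. Exit status is nonzero on any validation error.

suppressMessages({
  library(optparse)
  library(boldsim)
})

parser <- OptionParser(
  usage = "%prog {run|reference|sweep} [options]",
  option_list = list(
    make_option("--config", type = "character", default = NULL,
                help = "YAML/JSON run configuration (defaults used if absent)"),
    make_option("--seed", type = "integer", default = NULL,
                help = "RNG seed overriding the configured one"),
    make_option("--out", type = "character", default = ".",
                help = "output directory [default %default]"),
    make_option("--prefix", type = "character", default = "run",
                help = "output file prefix [default %default]"),
    make_option("--evolve", action = "store_true", default = FALSE,
                help = "reference model: update cooperators' strategies"),
    make_option("--lambdas", type = "character", default = "0.4,0.5,0.6,0.7,0.8,0.9",
                help = "sweep: comma-separated update rates [default %default]"),
    make_option("--levels", type = "character", default = "O1,O2,O3,O4",
                help = "sweep: comma-separated obstacle levels [default %default]"),
    make_option("--verbose", action = "store_true", default = FALSE,
                help = "log per-task progress")
  ))
parsed <- parse_args(parser, positional_arguments = 1L)
cmd <- parsed$args
opt <- parsed$options

run_main <- function() {
  cfg <- load_config(if (is.null(opt$config)) list() else opt$config)
  seed <- if (is.null(opt$seed)) cfg$seed else opt$seed
  rec <- switch(cmd,
    run = run_evolution(cfg$params, cfg$schedule, cfg$table, seed = seed),
    reference = run_reference_model(cfg$params, cfg$schedule, cfg$table,
                                    seed = seed, evolve = opt$evolve),
    sweep = NULL)
  if (cmd %in% c("run", "reference")) {
    if (opt$verbose) {
      message(sprintf("%s: %d tasks, seed %d", rec$variant,
                      nrow(rec$tasks), rec$seed))
    }
    paths <- export_records(rec, opt$out, prefix = opt$prefix,
                            window = cfg$stats_window)
    print(summarize_evolution(rec, window = cfg$stats_window))
    message("wrote ", paste(paths, collapse = ", "))
  } else if (cmd == "sweep") {
    lambdas <- as.numeric(strsplit(opt$lambdas, ",")[[1]])
    levels <- strsplit(opt$levels, ",")[[1]]
    sw <- run_sweep(cfg$params, lambdas, levels, replicates = cfg$replicates,
                    base_seed = seed, table = cfg$table,
                    n_tasks = cfg$n_tasks, window = cfg$stats_window)
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    rep_path <- file.path(opt$out, paste0(opt$prefix, "_sweep_replicates.csv"))
    cell_path <- file.path(opt$out, paste0(opt$prefix, "_sweep_cells.csv"))
    write.csv(sw$by_replicate, rep_path, row.names = FALSE)
    write.csv(sw$by_cell, cell_path, row.names = FALSE)
    print(sw)
    message("wrote ", rep_path, ", ", cell_path)
  } else {
    stop("unknown subcommand: ", cmd)
  }
}

status <- tryCatch({ run_main(); 0L },
                   error = function(e) {
                     message("error: ", conditionMessage(e)); 1L
                   })
quit(status = status)
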