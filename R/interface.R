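config_defaults <- function() {
  list(n_agents = 6L, benefit = 2, cost = 1, update_rate = 0.9,
       bold_threshold = 0.7, shy_threshold = 0.3,
       n_tasks = 200L, stats_window = 100L,
       schedule = list(fixed = "O1"), success_table = "default",
       model_variant = "personality", seed = 1L, replicates = 5L,
       output_dir = ".")
}

#' Load and validate a run configuration
#'
#' Accepts a path to a YAML or JSON file, or an inline named list. Missing
#' keys take the canonical experimental defaults (six agents, b = 2, c = 1,
#' 200 tasks, a 100-task statistics window, five replicates). Every
#' constraint is checked before any simulation starts and all violations are
#' reported together.
#'
#' Recognized keys: the [game_params()] fields, `n_tasks`, `stats_window`,
#' `schedule` (`list(fixed = "O2")` or
#' `list(changing = list(easy = "O1", hard = "O4"))`), `success_table`
#' (`"default"` or a mapping from obstacle level to a vector of `n_agents`
#' probabilities), `model_variant` (`"personality"`, `"reference_fixed"`,
#' `"reference_evolving"`), `seed`, `replicates`, `output_dir`.
#'
#' @param config File path or named list.
#' @return A `"run_config"` list with `params` (a [game_params()]),
#'   `schedule` (expanded label vector), `table` (a [success_table()]) and
#'   the remaining scalar settings.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a file path or a named list",
                             call. = FALSE)
  known <- names(config_defaults())
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(config_defaults(), config)
  # structured keys replace the default wholesale, never merge with it
  for (key in intersect(c("schedule", "success_table"), names(config))) {
    cfg[[key]] <- config[[key]]
  }
  # the default trailing window shrinks with short runs; an explicit
  # stats_window is validated as given
  if (!"stats_window" %in% names(config)) {
    cfg$stats_window <- min(cfg$stats_window, cfg$n_tasks)
  }

  problems <- character()
  params <- tryCatch(
    game_params(cfg$n_agents, cfg$benefit, cfg$cost, cfg$update_rate,
                cfg$bold_threshold, cfg$shy_threshold),
    error = function(e) {
      problems <<- c(problems, conditionMessage(e)); NULL
    })
  if (!is.numeric(cfg$n_tasks) || cfg$n_tasks < 1) {
    problems <- c(problems, "n_tasks must be a positive integer")
  }
  if (!is.numeric(cfg$stats_window) || cfg$stats_window < 1 ||
      cfg$stats_window > cfg$n_tasks) {
    problems <- c(problems, "stats_window must be between 1 and n_tasks")
  }
  if (!cfg$model_variant %in% c("personality", "reference_fixed",
                                "reference_evolving")) {
    problems <- c(problems, "model_variant must be one of personality, reference_fixed, reference_evolving")
  }
  if (!is.numeric(cfg$replicates) || cfg$replicates < 1) {
    problems <- c(problems, "replicates must be a positive integer")
  }

  schedule <- tryCatch({
    sc <- cfg$schedule
    if (!is.null(sc$fixed)) {
      make_schedule(fixed = sc$fixed, n_tasks = as.integer(cfg$n_tasks))
    } else if (!is.null(sc$changing)) {
      ch <- sc$changing
      make_schedule(changing = c(ch$easy, ch$hard),
                    n_tasks = as.integer(cfg$n_tasks))
    } else {
      stop("schedule must have a 'fixed' or 'changing' entry", call. = FALSE)
    }
  }, error = function(e) {
    problems <<- c(problems, paste0("schedule: ", conditionMessage(e))); NULL
  })

  table <- tryCatch({
    if (identical(cfg$success_table, "default")) {
      default_success_table(as.integer(cfg$n_agents))
    } else {
      m <- do.call(rbind, lapply(cfg$success_table, as.numeric))
      rownames(m) <- names(cfg$success_table)
      tab <- success_table(m)
      viol <- validate_success_table(tab)
      if (length(viol)) stop(paste(viol, collapse = "; "), call. = FALSE)
      tab
    }
  }, error = function(e) {
    problems <<- c(problems, paste0("success_table: ", conditionMessage(e)))
    NULL
  })

  if (length(problems)) {
    stop("invalid configuration: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(list(params = params, schedule = schedule, table = table,
                 n_tasks = as.integer(cfg$n_tasks),
                 stats_window = as.integer(cfg$stats_window),
                 model_variant = cfg$model_variant,
                 seed = as.integer(cfg$seed),
                 replicates = as.integer(cfg$replicates),
                 output_dir = cfg$output_dir),
            class = "run_config")
}

#' Run the model a configuration describes
#'
#' Dispatches to [run_evolution()] or [run_reference_model()] according to
#' the configuration's `model_variant`.
#'
#' @param config A `"run_config"` from [load_config()] (or anything
#'   [load_config()] accepts).
#' @param seed Optional seed overriding the configured one.
#' @return An `"evolution_record"`.
#' @export
run_from_config <- function(config, seed = NULL) {
  if (!inherits(config, "run_config")) config <- load_config(config)
  if (is.null(seed)) seed <- config$seed
  switch(config$model_variant,
    personality = run_evolution(config$params, config$schedule, config$table,
                                seed = seed),
    reference_fixed = run_reference_model(config$params, config$schedule,
                                          config$table, seed = seed,
                                          evolve = FALSE),
    reference_evolving = run_reference_model(config$params, config$schedule,
                                             config$table, seed = seed,
                                             evolve = TRUE))
}

fmt17 <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

#' Export an evolution record to CSV + JSON
#'
#' Writes a per-task CSV (RFC-4180, header row, floating point at 17
#' significant digits so values round-trip exactly) and a JSON run summary
#' holding the configuration, seed, initial state and the windowed summary
#' statistics. For reference-model records the `initiator` and
#' `decision_time` columns are empty by contract. The pair is read back
#' losslessly by [read_records()].
#'
#' @param record An `"evolution_record"`.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix; files are `<prefix>_tasks.csv` and
#'   `<prefix>_run.json`.
#' @param window Statistics window for the summary (see
#'   [summarize_evolution()]).
#' @return Invisibly, a named character vector with the two paths.
#' @export
export_records <- function(record, out_dir, prefix = "run", window = NULL) {
  stopifnot(inherits(record, "evolution_record"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  csv_path <- file.path(out_dir, paste0(prefix, "_tasks.csv"))
  json_path <- file.path(out_dir, paste0(prefix, "_run.json"))

  tk <- record$tasks
  num_cols <- names(tk)[vapply(tk, is.numeric, logical(1))]
  out <- tk
  for (cl in setdiff(num_cols, c("task_index", "initiator", "n_coop",
                                 "n_bold", "outcome"))) {
    out[[cl]] <- fmt17(tk[[cl]])
  }
  ok <- tryCatch({
    utils::write.csv(out, csv_path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) {
    stop(sprintf("failed to write '%s': %s", csv_path, conditionMessage(e)),
         call. = FALSE)
  })

  summary <- summarize_evolution(record, window = window)
  meta <- list(
    config = list(
      n_agents = record$params$n_agents, benefit = record$params$benefit,
      cost = record$params$cost, update_rate = record$params$update_rate,
      bold_threshold = record$params$bold_threshold,
      shy_threshold = record$params$shy_threshold,
      n_tasks = nrow(record$tasks)),
    variant = record$variant, seed = record$seed,
    schedule_levels = unique(record$schedule),
    initial_state = record$initial_state,
    summary = summary[setdiff(names(summary), "window")]
  )
  meta$summary$window <- summary$window
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(tasks = csv_path, run = json_path))
}

#' Read back an exported evolution record
#'
#' Inverse of [export_records()]: reconstructs the `"evolution_record"`
#' (configuration, seed, initial state, task table) from the CSV/JSON pair.
#'
#' @param csv_path Path to the `_tasks.csv` file.
#' @param json_path Path to the `_run.json` file.
#' @return An `"evolution_record"` field-for-field equal to the exported one.
#' @export
read_records <- function(csv_path, json_path) {
  for (p in c(csv_path, json_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  cfg <- meta$config
  params <- game_params(cfg$n_agents, cfg$benefit, cfg$cost, cfg$update_rate,
                        cfg$bold_threshold, cfg$shy_threshold)
  tk <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  n <- params$n_agents
  int_cols <- c("task_index", "initiator", "n_coop", "n_bold", "outcome")
  for (cl in int_cols) tk[[cl]] <- as.integer(tk[[cl]])
  dbl_cols <- c("decision_time", paste0("payoff_", seq_len(n)),
                paste0("trait_", seq_len(n)))
  for (cl in dbl_cols) tk[[cl]] <- as.numeric(tk[[cl]])
  new_evolution_record(params, meta$variant, as.integer(meta$seed),
                       tk$obstacle, as.numeric(meta$initial_state), tk)
}
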