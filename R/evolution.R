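#' Build an obstacle schedule
#'
#' A schedule assigns one obstacle level to each of the tasks in an evolution.
#' Two shapes are supported: a fixed level throughout, or the changing-tasks
#' protocol in which the first 60 tasks and the last 80 tasks are easy and the
#' middle block (tasks 61–120, 1-based) is hard.
#'
#' @param fixed A single obstacle level to repeat for every task.
#' @param changing Length-2 character vector `c(easy, hard)` for the
#'   60-easy / 60-hard / rest-easy protocol.
#' @param n_tasks Number of tasks in the evolution (default 200; the changing
#'   protocol requires at least 120).
#' @return Character vector of length `n_tasks` with obstacle labels.
#' @examples
#' sched <- make_schedule(changing = c("O1", "O4"))
#' table(sched)
#' @export
make_schedule <- function(fixed = NULL, changing = NULL, n_tasks = 200L) {
  stopifnot(n_tasks >= 1)
  known <- obstacle_levels()
  if (!is.null(fixed) && !is.null(changing)) {
    stop("give either 'fixed' or 'changing', not both", call. = FALSE)
  }
  if (!is.null(fixed)) {
    if (length(fixed) != 1L || !fixed %in% known) {
      stop("unknown obstacle level: ", paste(fixed, collapse = ", "),
           call. = FALSE)
    }
    return(rep(fixed, n_tasks))
  }
  if (!is.null(changing)) {
    if (length(changing) != 2L || !all(changing %in% known)) {
      stop("'changing' must be two known obstacle levels c(easy, hard)",
           call. = FALSE)
    }
    if (n_tasks < 120L) {
      stop("changing schedule needs at least 120 tasks", call. = FALSE)
    }
    return(c(rep(changing[1L], 60L), rep(changing[2L], 60L),
             rep(changing[1L], n_tasks - 120L)))
  }
  stop("give one of 'fixed' or 'changing'", call. = FALSE)
}

new_evolution_record <- function(params, variant, seed, schedule,
                                 initial_state, tasks) {
  structure(
    list(params = params, variant = variant, seed = seed, schedule = schedule,
         initial_state = initial_state, tasks = tasks),
    class = "evolution_record"
  )
}

#' @export
print.evolution_record <- function(x, ...) {
  cat(sprintf("Evolution record (%s): %d tasks, N = %d, lambda = %g, seed = %d\n",
              x$variant, nrow(x$tasks), x$params$n_agents,
              x$params$update_rate, x$seed))
  cat("Obstacles:", paste(unique(x$schedule), collapse = ", "), "\n")
  invisible(x)
}

record_colnames <- function(n) {
  c("task_index", "obstacle", "initiator", "n_coop", "n_bold", "outcome",
    "decision_time",
    paste0("role_", seq_len(n)),
    paste0("payoff_", seq_len(n)),
    paste0("trait_", seq_len(n)))
}

#' Run one evolution of the personality model
#'
#' Plays the stage game once per scheduled task, threading the initiator's
#' trait update from each task into the next. The run is fully determined by
#' `seed` and the configuration: the seed initializes the global RNG stream,
#' the initial traits (if not supplied) are drawn i.i.d. uniform on (0, 1)
#' from that stream, and every race, role draw and outcome draw consumes it
#' in task order.
#'
#' @param params A [game_params()] object.
#' @param schedule Character vector of obstacle labels from [make_schedule()].
#' @param table A [success_table()] covering every scheduled level; defaults
#'   to [default_success_table()].
#' @param seed Integer RNG seed.
#' @param initial_traits Optional numeric vector of starting boldness values
#'   in (0, 1); drawn uniformly when omitted.
#' @param race Initiator-selection mode passed to [play_stage_game()].
#' @return An `"evolution_record"`: the configuration, seed, schedule,
#'   initial traits and a data frame `tasks` with one row per task
#'   (task_index, obstacle, initiator, n_coop, n_bold, outcome,
#'   decision_time, per-agent roles, payoffs and post-update traits).
#' @examples
#' rec <- run_evolution(game_params(), make_schedule(fixed = "O1", n_tasks = 20),
#'                      seed = 1)
#' head(rec$tasks[, 1:7])
#' @export
run_evolution <- function(params, schedule,
                          table = default_success_table(params$n_agents),
                          seed = 1L, initial_traits = NULL,
                          race = c("explicit", "fast")) {
  stopifnot(inherits(params, "game_params"))
  race <- match.arg(race)
  missing_levels <- setdiff(unique(schedule), rownames(table$probabilities))
  if (length(missing_levels)) {
    stop("success table does not cover scheduled level(s): ",
         paste(missing_levels, collapse = ", "), call. = FALSE)
  }
  n <- params$n_agents
  n_tasks <- length(schedule)
  seed <- as.integer(seed)
  set.seed(seed)
  if (is.null(initial_traits)) initial_traits <- stats::runif(n)
  validate_traits(initial_traits, n)

  initiator <- integer(n_tasks); n_coop <- integer(n_tasks)
  n_bold <- integer(n_tasks); outcome <- integer(n_tasks)
  dtime <- numeric(n_tasks)
  roles <- matrix(NA_character_, n_tasks, n)
  payoffs <- matrix(NA_real_, n_tasks, n)
  traits <- matrix(NA_real_, n_tasks, n)

  s <- initial_traits
  for (k in seq_len(n_tasks)) {
    tr <- play_stage_game(s, schedule[k], table, params,
                          task_index = k - 1L, race = race)
    initiator[k] <- tr$initiator
    n_coop[k] <- tr$n_cooperators
    n_bold[k] <- tr$n_bold
    outcome[k] <- tr$outcome
    dtime[k] <- tr$decision_times[tr$initiator]
    roles[k, ] <- tr$roles
    payoffs[k, ] <- tr$payoffs
    traits[k, ] <- tr$traits_after
    s <- tr$traits_after
  }

  tasks <- data.frame(
    task_index = seq_len(n_tasks) - 1L, obstacle = schedule,
    initiator = initiator, n_coop = n_coop, n_bold = n_bold,
    outcome = outcome, decision_time = dtime,
    roles, payoffs, traits, stringsAsFactors = FALSE)
  names(tasks) <- record_colnames(n)
  new_evolution_record(params, "personality", seed, schedule,
                       initial_traits, tasks)
}

#' Run the reference model without personality traits
#'
#' In the reference model each agent's strategy \eqn{\hat{s}_i \in (0,1)} is
#' simply its probability of cooperating (pushing the obstacle); there is no
#' initiator, no decision time and no follower structure. Each task, agent
#' \eqn{i} cooperates with probability \eqn{\hat{s}_i}; the outcome is drawn
#' from the success table at the resulting cooperator count (zero cooperators
#' always fail), payoffs follow the snowdrift rule, and — if `evolve = TRUE` —
#' every cooperator updates its strategy with the shared reinforcement
#' \eqn{r} under the same update rule as the personality model. Without
#' evolution, strategies never change.
#'
#' @inheritParams run_evolution
#' @param evolve Logical; update cooperators' strategies after each task?
#' @param initial_probs Optional starting cooperation probabilities (uniform
#'   draws when omitted).
#' @return An `"evolution_record"` with variant `"reference_evolving"` or
#'   `"reference_fixed"`. `initiator` and `decision_time` columns are `NA` by
#'   contract; role labels are `"cooperator"` / `"defector"`; `trait_*`
#'   columns hold the cooperation probabilities after each task; `n_bold`
#'   counts strategies above the bold threshold.
#' @export
run_reference_model <- function(params, schedule,
                                table = default_success_table(params$n_agents),
                                seed = 1L, evolve = TRUE,
                                initial_probs = NULL) {
  stopifnot(inherits(params, "game_params"))
  missing_levels <- setdiff(unique(schedule), rownames(table$probabilities))
  if (length(missing_levels)) {
    stop("success table does not cover scheduled level(s): ",
         paste(missing_levels, collapse = ", "), call. = FALSE)
  }
  n <- params$n_agents
  n_tasks <- length(schedule)
  seed <- as.integer(seed)
  set.seed(seed)
  if (is.null(initial_probs)) initial_probs <- stats::runif(n)
  validate_traits(initial_probs, n)
  lam <- params$update_rate

  n_coop <- integer(n_tasks); n_bold <- integer(n_tasks)
  outcome <- integer(n_tasks)
  roles <- matrix(NA_character_, n_tasks, n)
  payoffs <- matrix(NA_real_, n_tasks, n)
  traits <- matrix(NA_real_, n_tasks, n)

  s <- initial_probs
  for (k in seq_len(n_tasks)) {
    coop <- stats::runif(n) < s
    nc <- sum(coop)
    r <- if (nc == 0L) 0L else sample_outcome(table, schedule[k], nc)
    if (evolve && nc > 0L) s[coop] <- clamp_unit(r * lam + s[coop] * (1 - lam))
    n_coop[k] <- nc
    n_bold[k] <- count_bold(s, params$bold_threshold)
    outcome[k] <- r
    roles[k, ] <- ifelse(coop, "cooperator", "defector")
    payoffs[k, ] <- r * params$benefit - params$cost * coop
    traits[k, ] <- s
  }

  tasks <- data.frame(
    task_index = seq_len(n_tasks) - 1L, obstacle = schedule,
    initiator = NA_integer_, n_coop = n_coop, n_bold = n_bold,
    outcome = outcome, decision_time = NA_real_,
    roles, payoffs, traits, stringsAsFactors = FALSE)
  names(tasks) <- record_colnames(n)
  new_evolution_record(params,
                       if (evolve) "reference_evolving" else "reference_fixed",
                       seed, schedule, initial_probs, tasks)
}

#' Derive a replicate seed
#'
#' Deterministic, collision-sparse mapping from (base seed, update rate,
#' obstacle level, replicate index) to a seed below 2^31, so sweeps are
#' reproducible cell by cell.
#'
#' @param base_seed Integer base seed of the sweep.
#' @param lambda Update rate of the cell.
#' @param level Obstacle level label of the cell.
#' @param replicate Replicate index (1-based).
#' @return A positive integer seed.
#' @export
derive_seed <- function(base_seed, lambda, level, replicate) {
  lvl <- match(level, obstacle_levels())
  if (is.na(lvl)) stop("unknown obstacle level: ", level, call. = FALSE)
  raw <- (as.double(base_seed) + 1299709 * replicate + 104729 * lvl +
            round(1000 * lambda)) %% 2147483647
  as.integer(raw) + 1L
}

#' Replicate sweep over update rates and difficulty levels
#'
#' Runs `replicates` independent evolutions for every (lambda, level) cell of
#' the grid, each on a fixed schedule of that level, summarizes each run over
#' the trailing statistics window, and aggregates per-cell means and standard
#' errors. Replicate seeds come from [derive_seed()], so the whole table is
#' reproducible from `base_seed`.
#'
#' @param params A [game_params()] object; its `update_rate` is overridden by
#'   each grid value.
#' @param lambdas Numeric vector of update rates (the canonical grid is
#'   0.4–0.9 in steps of 0.1).
#' @param levels Character vector of obstacle levels.
#' @param replicates Runs per cell (default 5).
#' @param base_seed Integer seed from which replicate seeds are derived.
#' @param table Success table used for every run.
#' @param n_tasks Tasks per evolution (default 200).
#' @param window Trailing statistics window length (default 100).
#' @return A `"sweep_result"` list with two data frames: `by_replicate` (one
#'   row per lambda x level x replicate, columns from
#'   [summarize_evolution()]) and `by_cell` (per-cell mean and standard error
#'   of each statistic).
#' @export
run_sweep <- function(params, lambdas, levels, replicates = 5L,
                      base_seed = 1L,
                      table = default_success_table(params$n_agents),
                      n_tasks = 200L, window = 100L) {
  stopifnot(length(lambdas) >= 1, length(levels) >= 1, replicates >= 1)
  rows <- list()
  for (lam in lambdas) {
    p <- game_params(n_agents = params$n_agents, benefit = params$benefit,
                     cost = params$cost, update_rate = lam,
                     bold_threshold = params$bold_threshold,
                     shy_threshold = params$shy_threshold)
    for (lvl in levels) {
      sched <- make_schedule(fixed = lvl, n_tasks = n_tasks)
      for (j in seq_len(replicates)) {
        sd_j <- derive_seed(base_seed, lam, lvl, j)
        rec <- run_evolution(p, sched, table, seed = sd_j)
        ss <- summarize_evolution(rec, window = window)
        rows[[length(rows) + 1L]] <- data.frame(
          lambda = lam, level = lvl, replicate = j, seed = sd_j,
          mean_trait = ss$mean_trait, mean_n_bold = ss$mean_n_bold,
          mean_n_coop = ss$mean_n_coop, diversity = ss$diversity,
          mean_decision_time = ss$mean_decision_time,
          mean_cost = ss$mean_cost, mean_payoff = ss$mean_payoff,
          success_rate = ss$success_rate, stringsAsFactors = FALSE)
      }
    }
  }
  by_replicate <- do.call(rbind, rows)
  stat_cols <- c("mean_trait", "mean_n_bold", "mean_n_coop", "diversity",
                 "mean_decision_time", "mean_cost", "mean_payoff",
                 "success_rate")
  cells <- unique(by_replicate[, c("lambda", "level")])
  agg <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- by_replicate[by_replicate$lambda == cells$lambda[i] &
                          by_replicate$level == cells$level[i], ]
    means <- vapply(sub[stat_cols], mean, numeric(1))
    ses <- vapply(sub[stat_cols],
                  function(x) stats::sd(x) / sqrt(length(x)), numeric(1))
    out <- data.frame(lambda = cells$lambda[i], level = cells$level[i],
                      replicates = nrow(sub), stringsAsFactors = FALSE)
    for (s in stat_cols) {
      out[[s]] <- means[[s]]
      out[[paste0(s, "_se")]] <- ses[[s]]
    }
    out
  })
  by_cell <- do.call(rbind, agg)
  structure(list(by_replicate = by_replicate, by_cell = by_cell),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep: %d replicate runs over %d cells\n",
              nrow(x$by_replicate), nrow(x$by_cell)))
  print(x$by_cell[, c("lambda", "level", "mean_n_coop", "mean_n_bold",
                      "diversity", "success_rate")], digits = 3)
  invisible(x)
}
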