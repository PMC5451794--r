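# Forced environments: every task succeeds / fails regardless of cooperators.
ones_table <- function(n = 6L) constant_success_table(1, n)
zeros_table <- function(n = 6L) constant_success_table(0, n)

# Minimal hand-built personality record for metric tests: cycle of initiators,
# constant cooperator count, constant outcome. Payoffs are consistent with the
# snowdrift rule so conservation identities hold.
fake_record <- function(n_tasks = 200L, n = 6L, n_coop = 4L, outcome = 1L,
                        initiators = rep(seq_len(n), length.out = n_tasks),
                        params = game_params()) {
  roles <- matrix("free_rider", n_tasks, n)
  payoffs <- matrix(outcome * params$benefit, n_tasks, n)
  for (k in seq_len(n_tasks)) {
    coop <- unique(c(initiators[k], seq_len(n_coop)))[seq_len(n_coop)]
    roles[k, coop] <- "follower"
    roles[k, initiators[k]] <- "initiator"
    payoffs[k, coop] <- outcome * params$benefit - params$cost
  }
  traits <- matrix(0.5, n_tasks, n)
  tasks <- data.frame(
    task_index = seq_len(n_tasks) - 1L,
    obstacle = rep("O1", n_tasks),
    initiator = initiators,
    n_coop = rep(as.integer(n_coop), n_tasks),
    n_bold = rep(0L, n_tasks),
    outcome = rep(as.integer(outcome), n_tasks),
    decision_time = rep(1, n_tasks),
    roles, payoffs, traits, stringsAsFactors = FALSE)
  names(tasks) <- boldsim:::record_colnames(n)
  boldsim:::new_evolution_record(params, "personality", 1L,
                                 tasks$obstacle, rep(0.5, n),
                                 tasks)
}
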