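test_that("schedules expand to one obstacle label per task", {
  fixed <- make_schedule(fixed = "O2")
  expect_length(fixed, 200)
  expect_true(all(fixed == "O2"))

  ch <- make_schedule(changing = c("O1", "O4"))
  expect_length(ch, 200)
  expect_true(all(ch[1:60] == "O1"))
  expect_true(all(ch[61:120] == "O4"))
  expect_true(all(ch[121:200] == "O1"))

  expect_error(make_schedule(fixed = "O9"), "unknown obstacle")
  expect_error(make_schedule(changing = c("O1", "O9")), "known obstacle")
  expect_error(make_schedule(changing = c("O1", "O4"), n_tasks = 100),
               "at least 120")
  expect_error(make_schedule(), "one of")
  expect_error(make_schedule(fixed = "O1", changing = c("O1", "O4")),
               "not both")
})

test_that("forced-success single-agent run follows the closed-form trajectory", {
  for (lam in c(0.4, 0.9)) {
    p <- game_params(n_agents = 1, update_rate = lam)
    rec <- run_evolution(p, make_schedule(fixed = "O1", n_tasks = 50),
                         ones_table(1), seed = 1, initial_traits = 0.5)
    k <- seq_len(50)
    closed <- 1 + (0.5 - 1) * (1 - lam)^k
    expect_equal(rec$tasks$trait_1, closed, tolerance = 1e-12)
    expect_true(all(rec$tasks$outcome == 1L))
    expect_true(all(rec$tasks$n_coop == 1L))
  }
})

test_that("forced failure makes mean boldness nonincreasing", {
  p <- game_params()
  rec <- run_evolution(p, make_schedule(fixed = "O3", n_tasks = 150),
                       zeros_table(6), seed = 3)
  mean_s <- rowMeans(as.matrix(rec$tasks[paste0("trait_", 1:6)]))
  expect_true(all(diff(mean_s) <= 0))
  expect_true(all(rec$tasks$outcome == 0L))
})

test_that("identical seed and configuration reproduce the task stream", {
  p <- game_params(update_rate = 0.6)
  sched <- make_schedule(fixed = "O2", n_tasks = 80)
  a <- run_evolution(p, sched, seed = 99)
  b <- run_evolution(p, sched, seed = 99)
  expect_identical(a$tasks, b$tasks)
  expect_identical(a$initial_state, b$initial_state)
  c <- run_evolution(p, sched, seed = 100)
  expect_false(identical(a$tasks, c$tasks))
})

test_that("traits thread between tasks: only the initiator's entry changes", {
  p <- game_params()
  rec <- run_evolution(p, make_schedule(fixed = "O2", n_tasks = 120), seed = 8)
  traits <- as.matrix(rec$tasks[paste0("trait_", 1:6)])
  for (k in 2:nrow(traits)) {
    init <- rec$tasks$initiator[k]
    expect_equal(traits[k, -init], traits[k - 1, -init],
                 ignore_attr = TRUE)
  }
})

test_that("run rejects a schedule its success table does not cover", {
  p <- game_params()
  tab <- success_table(matrix(1, 1, 6, dimnames = list("O1", NULL)))
  expect_error(run_evolution(p, make_schedule(fixed = "O4"), tab, seed = 1),
               "does not cover")
  expect_error(run_reference_model(p, make_schedule(fixed = "O4"), tab,
                                   seed = 1),
               "does not cover")
})

test_that("reference model without evolution keeps strategies fixed", {
  p <- game_params()
  rec <- run_reference_model(p, make_schedule(fixed = "O1", n_tasks = 60),
                             seed = 5, evolve = FALSE)
  expect_identical(rec$variant, "reference_fixed")
  traits <- as.matrix(rec$tasks[paste0("trait_", 1:6)])
  expect_true(all(apply(traits, 2, function(x) length(unique(x)) == 1)))
  expect_equal(traits[1, ], rec$initial_state, ignore_attr = TRUE)
  expect_true(all(is.na(rec$tasks$initiator)))
  expect_true(all(is.na(rec$tasks$decision_time)))
})

test_that("evolving reference strategies drift with the shared reinforcement", {
  p <- game_params()
  up <- run_reference_model(p, make_schedule(fixed = "O1", n_tasks = 150),
                            ones_table(6), seed = 6, evolve = TRUE)
  traits_up <- as.matrix(up$tasks[paste0("trait_", 1:6)])
  expect_true(all(apply(traits_up, 2, function(x) all(diff(x) >= 0))))
  expect_true(all(traits_up[150, ] > 0.99))

  down <- run_reference_model(p, make_schedule(fixed = "O1", n_tasks = 150),
                              zeros_table(6), seed = 7, evolve = TRUE)
  traits_down <- as.matrix(down$tasks[paste0("trait_", 1:6)])
  expect_true(all(apply(traits_down, 2, function(x) all(diff(x) <= 0))))
})

test_that("a cooperator-free reference task fails with zero payoff for all", {
  p <- game_params()
  rec <- run_reference_model(p, make_schedule(fixed = "O1", n_tasks = 100),
                             seed = 9, evolve = FALSE,
                             initial_probs = rep(1e-4, 6))
  empty <- rec$tasks$n_coop == 0L
  expect_gt(sum(empty), 0)
  expect_true(all(rec$tasks$outcome[empty] == 0L))
  payoffs <- as.matrix(rec$tasks[paste0("payoff_", 1:6)])
  expect_true(all(payoffs[empty, ] == 0))
})

test_that("sweep produces one row per replicate plus per-cell aggregates", {
  p <- game_params()
  sw <- run_sweep(p, c(0.4, 0.9), c("O1", "O4"), replicates = 2,
                  base_seed = 17, n_tasks = 40, window = 20)
  expect_equal(nrow(sw$by_replicate), 8)
  expect_equal(nrow(sw$by_cell), 4)
  expect_true(all(c("mean_n_coop", "mean_n_coop_se") %in% names(sw$by_cell)))

  # deterministic replicate seeding: rerun reproduces the table
  sw2 <- run_sweep(p, c(0.4, 0.9), c("O1", "O4"), replicates = 2,
                   base_seed = 17, n_tasks = 40, window = 20)
  expect_identical(sw$by_replicate, sw2$by_replicate)

  # forced success drives the success-rate column to 1 everywhere
  sw3 <- run_sweep(p, 0.9, "O2", replicates = 2, base_seed = 3,
                   table = ones_table(6), n_tasks = 40, window = 20)
  expect_true(all(sw3$by_replicate$success_rate == 1))
})

test_that("derived replicate seeds are deterministic, distinct and 32-bit", {
  s1 <- derive_seed(123, 0.4, "O1", 1)
  expect_identical(s1, derive_seed(123, 0.4, "O1", 1))
  grid <- expand.grid(lam = seq(0.4, 0.9, 0.1), lvl = obstacle_levels(),
                      rep = 1:5)
  seeds <- mapply(derive_seed, 123, grid$lam, grid$lvl, grid$rep)
  expect_equal(length(unique(seeds)), nrow(grid))
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_error(derive_seed(1, 0.4, "O7", 1), "unknown obstacle")
})
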