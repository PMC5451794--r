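test_that("game parameter validation enforces the snowdrift constraints", {
  expect_s3_class(game_params(), "game_params")
  expect_error(game_params(benefit = 2, cost = 3), "benefit must exceed cost")
  expect_error(game_params(update_rate = 1), "update_rate")
  expect_error(game_params(update_rate = 0), "update_rate")
  expect_error(game_params(n_agents = 0), "n_agents")
  expect_error(game_params(bold_threshold = 0.3, shy_threshold = 0.7),
               "thresholds")
})

test_that("decision times are exponential with rate equal to boldness", {
  set.seed(101)
  draws <- sample_decision_times(rep(0.5, 1e5))
  expect_true(all(draws >= 0))
  # analytic mean 1/0.5 = 2, sd = 2, so 4 standard errors of the sample mean
  expect_lt(abs(mean(draws) - 2), 4 * 2 / sqrt(1e5))

  slow <- sample_decision_times(rep(0.2, 1e5))
  fast <- sample_decision_times(rep(0.8, 1e5))
  # means 1/0.2 = 5 vs 1/0.8 = 1.25: the bold agent decides 4x sooner
  expect_lt(abs(mean(fast) / mean(slow) - 0.25), 0.02)

  expect_error(sample_decision_times(numeric(0)), "nonempty")
  expect_error(sample_decision_times(c(0.5, 0)), "strictly in")
  expect_error(sample_decision_times(c(0.5, 1)), "strictly in")
})

test_that("initiator is the argmin of decision times, ties to lowest index", {
  expect_identical(select_initiator(c(3.2, 1.1, 5.0)), 2L)
  expect_identical(select_initiator(0.7), 1L)
  expect_identical(select_initiator(c(2.0, 2.0)), 1L)
  expect_error(select_initiator(numeric(0)), "nonempty")
  expect_error(select_initiator(c(1, -1)), "nonnegative")
})

test_that("initiator probability is proportional to boldness", {
  expect_equal(initiator_distribution(rep(0.4, 6)), rep(1 / 6, 6))
  expect_equal(initiator_distribution(c(0.6, 0.3)), c(2 / 3, 1 / 3))
  expect_error(initiator_distribution(c(0.5, 1.2)), "strictly in")

  # Monte Carlo: race winners follow s_m / sum(s)
  traits <- c(0.1, 0.2, 0.3, 0.4)
  set.seed(202)
  wins <- integer(4)
  for (i in seq_len(2e4)) {
    w <- select_initiator(sample_decision_times(traits))
    wins[w] <- wins[w] + 1L
  }
  gof <- chisq.test(wins, p = initiator_distribution(traits))
  expect_gt(gof$p.value, 0.001)
})

test_that("non-initiators follow with probability one minus boldness squared", {
  # one initiator plus 1e5 identical non-initiators with s = 0.6
  traits <- c(0.5, rep(0.6, 1e5))
  set.seed(303)
  roles <- assign_roles(traits, 1L)
  expect_identical(roles[1], "initiator")
  p_follow <- mean(roles[-1] == "follower")
  se <- sqrt(0.64 * 0.36 / 1e5)
  expect_lt(abs(p_follow - 0.64), 3 * se)

  # very shy non-initiators essentially always follow
  set.seed(304)
  shy_roles <- assign_roles(c(0.5, rep(1e-6, 1e4)), 1L)
  expect_true(all(shy_roles[-1] == "follower"))

  expect_identical(assign_roles(0.5, 1L), "initiator")
  expect_error(assign_roles(c(0.5, 0.5), 3L), "out of range")
})

test_that("snowdrift payoffs split by cooperation and outcome", {
  p <- game_params(benefit = 2, cost = 1)
  roles <- c("initiator", "follower", "free_rider")
  expect_equal(compute_payoffs(roles, 1, p), c(1, 1, 2))
  expect_equal(compute_payoffs(roles, 0, p), c(-1, -1, 0))
  all_c <- c("initiator", rep("follower", 5))
  expect_equal(sum(compute_payoffs(all_c, 1, p)), 6 * (2 - 1))
  expect_error(compute_payoffs(c("initiator", "bystander"), 1, p),
               "unknown role")
  expect_error(compute_payoffs(rep("follower", 3), 1, p), "exactly one")
  expect_error(compute_payoffs(roles, 2, p), "0 or 1")
})

test_that("reinforcement update moves only the initiator's trait", {
  expect_equal(update_initiator_trait(0.5, 1L, 1, game_params(update_rate = 0.9)),
               0.95)
  expect_equal(update_initiator_trait(0.5, 1L, 0, game_params(update_rate = 0.4)),
               0.30)
  expect_equal(update_initiator_trait(0.8, 1L, 1, game_params(update_rate = 0.4)),
               0.88)
  s <- update_initiator_trait(c(0.5, 0.2, 0.9), 2L, 1,
                              game_params(n_agents = 3, update_rate = 0.4))
  expect_equal(s, c(0.5, 0.4 + 0.2 * 0.6, 0.9))
})

test_that("trait closure holds under arbitrary update sequences", {
  set.seed(404)
  inside <- TRUE
  for (rep in 1:50) {
    p <- game_params(n_agents = 1, update_rate = runif(1, 0.01, 0.99))
    s <- runif(1)
    for (k in 1:200) {
      s <- update_initiator_trait(s, 1L, rbinom(1, 1, 0.5), p)
      inside <- inside && s > 0 && s < 1
    }
  }
  expect_true(inside)
})

test_that("a stage game composes race, roles, outcome, payoffs and update", {
  p1 <- game_params(n_agents = 1)
  set.seed(505)
  tr <- play_stage_game(0.5, "O1", ones_table(1), p1)
  expect_equal(tr$n_cooperators, 1L)
  expect_equal(tr$outcome, 1L)
  expect_equal(tr$payoffs, p1$benefit - p1$cost)
  expect_gt(tr$traits_after, 0.5)

  # forced failure strictly lowers the initiator's trait
  p6 <- game_params()
  set.seed(506)
  s0 <- runif(6, 0.2, 0.8)
  tr0 <- play_stage_game(s0, "O3", zeros_table(6), p6)
  expect_equal(tr0$outcome, 0L)
  expect_lt(tr0$traits_after[tr0$initiator], s0[tr0$initiator])
  expect_equal(tr0$traits_after[-tr0$initiator], s0[-tr0$initiator])

  # determinism: same seed, same configuration, identical record
  set.seed(507); a <- play_stage_game(s0, "O1", default_success_table(6), p6)
  set.seed(507); b <- play_stage_game(s0, "O1", default_success_table(6), p6)
  expect_identical(a, b)
})

test_that("fast race mode reproduces the initiator law", {
  traits <- c(0.1, 0.2, 0.3, 0.4)
  p <- game_params(n_agents = 4)
  tab <- ones_table(4)
  set.seed(606)
  wins <- integer(4)
  times <- numeric(2e4)
  na_ok <- TRUE
  for (i in seq_len(2e4)) {
    tr <- play_stage_game(traits, "O1", tab, p, race = "fast")
    wins[tr$initiator] <- wins[tr$initiator] + 1L
    times[i] <- tr$decision_times[tr$initiator]
    na_ok <- na_ok && all(is.na(tr$decision_times[-tr$initiator]))
  }
  expect_true(na_ok)
  gof <- chisq.test(wins, p = initiator_distribution(traits))
  expect_gt(gof$p.value, 0.001)
  # winning time follows the exponential-minimum law, mean 1/sum(s) = 1
  expect_lt(abs(mean(times) - 1), 4 / sqrt(2e4))
})
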