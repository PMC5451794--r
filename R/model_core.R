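#' Sample decision times for the initiator race
#'
#' Each agent \eqn{i} draws an independent exponential decision time with rate
#' equal to its boldness \eqn{s_i} (mean \eqn{1/s_i}): bolder agents tend to
#' decide sooner. Draws come from the current global RNG stream; seed the
#' stream (or use [run_evolution()]) for reproducibility.
#'
#' @param traits Numeric vector of boldness values, each strictly in (0, 1).
#' @return Numeric vector of nonnegative decision times, one per agent.
#' @examples
#' set.seed(1)
#' sample_decision_times(c(0.2, 0.8))
#' @export
sample_decision_times <- function(traits) {
  validate_traits(traits)
  stats::rexp(length(traits), rate = traits)
}

#' Select the initiator from a vector of decision times
#'
#' The agent with the smallest decision time initiates the collective action.
#' Ties (probability zero under continuous sampling, but possible for
#' degenerate inputs) break deterministically to the lowest agent index.
#'
#' @param decision_times Nonempty numeric vector of nonnegative times.
#' @return Integer index of the initiator.
#' @export
select_initiator <- function(decision_times) {
  if (!is.numeric(decision_times) || length(decision_times) == 0L ||
      anyNA(decision_times) || any(decision_times < 0)) {
    stop("decision_times must be a nonempty vector of nonnegative numbers",
         call. = FALSE)
  }
  which.min(decision_times)
}

#' Theoretical initiator probabilities
#'
#' For exponential decision times with rates \eqn{s_i}, the probability that
#' agent \eqn{m} wins the race is \eqn{s_m / \sum_i s_i}: the chance of
#' initiating is proportional to boldness.
#'
#' @inheritParams sample_decision_times
#' @return Numeric probability vector summing to 1.
#' @examples
#' initiator_distribution(c(0.6, 0.3))  # 2/3, 1/3
#' @export
initiator_distribution <- function(traits) {
  validate_traits(traits)
  traits / sum(traits)
}

#' Assign follower and free-rider roles around an initiator
#'
#' Given the initiator, each of the other \eqn{N - 1} agents independently
#' becomes a follower (joining the push) with probability \eqn{1 - s_i^2} and
#' a free-rider with probability \eqn{s_i^2}: bolder agents are less
#' responsive to someone else's initiative.
#'
#' @inheritParams sample_decision_times
#' @param initiator Integer index of the initiating agent.
#' @return Character vector of roles, one per agent, from
#'   `"initiator"`, `"follower"`, `"free_rider"`.
#' @export
assign_roles <- function(traits, initiator) {
  validate_traits(traits)
  n <- length(traits)
  if (!is.numeric(initiator) || length(initiator) != 1L || is.na(initiator) ||
      initiator < 1 || initiator > n || initiator != round(initiator)) {
    stop("initiator index out of range", call. = FALSE)
  }
  roles <- character(n)
  roles[initiator] <- "initiator"
  others <- setdiff(seq_len(n), initiator)
  if (length(others)) {
    u <- stats::runif(length(others))
    roles[others] <- ifelse(u < traits[others]^2, "free_rider", "follower")
  }
  roles
}

#' Snowdrift payoffs for one task
#'
#' Cooperators (the initiator and its followers) receive \eqn{r b - c};
#' free-riders receive \eqn{r b}, where \eqn{r = 1} if the group accomplished
#' the task and 0 otherwise. With the default \eqn{b = 2}, \eqn{c = 1}, a
#' successful task pays cooperators 1 and free-riders 2; a failed task costs
#' cooperators 1 and free-riders nothing.
#'
#' @param roles Character role vector as returned by [assign_roles()].
#' @param outcome Binary task outcome \eqn{r} (0 or 1).
#' @param params A [game_params()] object.
#' @return Numeric payoff vector, one entry per agent.
#' @export
compute_payoffs <- function(roles, outcome, params) {
  stopifnot(inherits(params, "game_params"))
  if (!outcome %in% c(0, 1)) stop("outcome must be 0 or 1", call. = FALSE)
  ok <- roles %in% c("initiator", "follower", "free_rider")
  if (!all(ok)) stop("unknown role label(s): ",
                     paste(unique(roles[!ok]), collapse = ", "), call. = FALSE)
  if (sum(roles == "initiator") != 1L) {
    stop("roles must contain exactly one initiator", call. = FALSE)
  }
  coop <- roles != "free_rider"
  outcome * params$benefit - params$cost * coop
}

#' Reinforcement update of the initiator's boldness
#'
#' After a task, only the initiator's trait changes:
#' \deqn{s_j \leftarrow r\lambda + s_j (1 - \lambda),}
#' pulling it toward 1 after a success (\eqn{r = 1}) and toward 0 after a
#' failure. Starting inside (0, 1) with \eqn{\lambda \in (0, 1)}, the trait
#' stays inside (0, 1) forever.
#'
#' @inheritParams assign_roles
#' @param outcome Binary reinforcement variable \eqn{r}.
#' @param params A [game_params()] object supplying \eqn{\lambda}.
#' @return The full trait vector with the initiator's entry updated.
#' @examples
#' p <- game_params(update_rate = 0.9)
#' update_initiator_trait(c(0.5, 0.4), 1, 1, p)  # first trait -> 0.95
#' @export
update_initiator_trait <- function(traits, initiator, outcome, params) {
  stopifnot(inherits(params, "game_params"))
  validate_traits(traits)
  if (!outcome %in% c(0, 1)) stop("outcome must be 0 or 1", call. = FALSE)
  if (initiator < 1 || initiator > length(traits)) {
    stop("initiator index out of range", call. = FALSE)
  }
  lam <- params$update_rate
  traits[initiator] <- clamp_unit(outcome * lam + traits[initiator] * (1 - lam))
  traits
}

# Mathematically the update keeps traits strictly inside (0, 1), but in double
# precision a long success (failure) streak can round the trait to exactly 1
# (underflow to 0). Clamp to the nearest representable interior values so the
# open-interval invariant also holds numerically.
clamp_unit <- function(x) {
  pmin(pmax(x, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Play one stage game (a single foraging task)
#'
#' Runs the full task pipeline: initiator race, role assignment, cooperator
#' count, Bernoulli outcome from the success model, snowdrift payoffs, and the
#' initiator's trait update.
#'
#' With `race = "explicit"` (default) all \eqn{N} decision times are sampled
#' and recorded — the winning decision time is itself a reported statistic.
#' `race = "fast"` samples the initiator directly from its marginal law
#' (probability proportional to boldness) and the winning time from the
#' exponential-minimum law (rate \eqn{\sum_i s_i}); the two modes are
#' distributionally equivalent but the fast mode leaves non-winning decision
#' times unrecorded.
#'
#' @inheritParams sample_decision_times
#' @param obstacle Obstacle difficulty label (e.g. `"O1"`).
#' @param table A [success_table()] covering `obstacle`.
#' @param params A [game_params()] object.
#' @param task_index Integer index stored in the returned record (0-based).
#' @param race `"explicit"` or `"fast"` (see Details).
#' @return A `"task_record"` list: `task_index`, `obstacle`, `decision_times`,
#'   `initiator`, `roles`, `n_cooperators`, `n_bold`, `outcome`, `payoffs`,
#'   `traits_after`.
#' @export
play_stage_game <- function(traits, obstacle, table, params, task_index = 0L,
                            race = c("explicit", "fast")) {
  race <- match.arg(race)
  validate_traits(traits, params$n_agents)
  n <- length(traits)
  if (race == "explicit") {
    times <- sample_decision_times(traits)
    initiator <- select_initiator(times)
  } else {
    initiator <- sample.int(n, 1L, prob = traits)
    times <- rep(NA_real_, n)
    times[initiator] <- stats::rexp(1L, rate = sum(traits))
  }
  roles <- assign_roles(traits, initiator)
  n_coop <- sum(roles != "free_rider")
  outcome <- sample_outcome(table, obstacle, n_coop)
  payoffs <- compute_payoffs(roles, outcome, params)
  traits_after <- update_initiator_trait(traits, initiator, outcome, params)
  structure(
    list(task_index = as.integer(task_index), obstacle = obstacle,
         decision_times = times, initiator = initiator, roles = roles,
         n_cooperators = n_coop,
         n_bold = count_bold(traits_after, params$bold_threshold),
         outcome = outcome, payoffs = payoffs, traits_after = traits_after),
    class = "task_record"
  )
}
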