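#' Game parameters for the snowdrift foraging game
#'
#' Bundles the stage-game constants: group size \eqn{N}, the snowdrift benefit
#' \eqn{b} and cooperation cost \eqn{c}, the reinforcement update rate
#' \eqn{\lambda}, and the boldness thresholds that classify agents as bold or
#' shy. Defaults are the reference experimental settings: a six-agent group
#' with \eqn{b = 2}, \eqn{c = 1} and a large update rate.
#'
#' @param n_agents Integer, number of agents \eqn{N} (at least 1).
#' @param benefit Benefit \eqn{b > c} every agent receives when the task
#'   succeeds.
#' @param cost Cost \eqn{c > 0} a cooperator pays for pushing the obstacle.
#' @param update_rate Learning rate \eqn{\lambda} of the reinforcement update,
#'   strictly inside (0, 1).
#' @param bold_threshold An agent with trait above this value counts as bold.
#' @param shy_threshold An agent with trait below this value counts as shy.
#'
#' @return An object of class `"game_params"`: a validated list with the six
#'   fields above.
#' @examples
#' p <- game_params()
#' p$benefit - p$cost  # the snowdrift margin
#' @export
game_params <- function(n_agents = 6L, benefit = 2, cost = 1, update_rate = 0.9,
                        bold_threshold = 0.7, shy_threshold = 0.3) {
  problems <- character()
  if (!is.numeric(n_agents) || length(n_agents) != 1L || n_agents < 1 ||
      n_agents != round(n_agents)) {
    problems <- c(problems, "n_agents must be a single integer >= 1")
  }
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0) {
    problems <- c(problems, "cost must be a single positive number")
  }
  if (!is.numeric(benefit) || length(benefit) != 1L || benefit <= cost) {
    problems <- c(problems, "benefit must exceed cost (snowdrift requires b > c > 0)")
  }
  if (!is.numeric(update_rate) || length(update_rate) != 1L ||
      update_rate <= 0 || update_rate >= 1) {
    problems <- c(problems, "update_rate must lie strictly in (0, 1)")
  }
  if (!is.numeric(shy_threshold) || !is.numeric(bold_threshold) ||
      length(shy_threshold) != 1L || length(bold_threshold) != 1L ||
      shy_threshold <= 0 || bold_threshold >= 1 ||
      shy_threshold >= bold_threshold) {
    problems <- c(problems, "thresholds must satisfy 0 < shy_threshold < bold_threshold < 1")
  }
  if (length(problems)) {
    stop("invalid game parameters: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(
    list(n_agents = as.integer(n_agents), benefit = benefit, cost = cost,
         update_rate = update_rate, bold_threshold = bold_threshold,
         shy_threshold = shy_threshold),
    class = "game_params"
  )
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf(
    "Snowdrift foraging game: N = %d, b = %g, c = %g, lambda = %g (bold > %g, shy < %g)\n",
    x$n_agents, x$benefit, x$cost, x$update_rate,
    x$bold_threshold, x$shy_threshold))
  invisible(x)
}

#' Validate a vector of boldness traits
#'
#' Traits live in the open unit interval: the exponential race needs a strictly
#' positive rate, and the reinforcement update never reaches 0 or 1, so both
#' endpoints are rejected exactly.
#'
#' @param traits Numeric vector of boldness values \eqn{s_i}.
#' @param n_agents Optional expected length.
#' @return The trait vector, invisibly, after validation.
#' @export
validate_traits <- function(traits, n_agents = NULL) {
  if (!is.numeric(traits) || length(traits) == 0L) {
    stop("traits must be a nonempty numeric vector", call. = FALSE)
  }
  if (anyNA(traits) || any(traits <= 0) || any(traits >= 1)) {
    stop("every boldness trait must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.null(n_agents) && length(traits) != n_agents) {
    stop(sprintf("expected %d traits, got %d", n_agents, length(traits)),
         call. = FALSE)
  }
  invisible(traits)
}
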