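#' Count bold / shy agents
#'
#' An agent is bold when its trait is strictly above the bold threshold and
#' shy when strictly below the shy threshold (agents in between are neither).
#'
#' @param traits Numeric vector of boldness values.
#' @param threshold Classification threshold (defaults 0.7 bold, 0.3 shy).
#' @return Integer count.
#' @export
count_bold <- function(traits, threshold = 0.7) sum(traits > threshold)

#' @rdname count_bold
#' @export
count_shy <- function(traits, threshold = 0.3) sum(traits < threshold)

resolve_window <- function(record, window) {
  n <- nrow(record$tasks)
  if (is.null(window)) window <- min(100L, n)
  if (length(window) == 1L) {
    len <- as.integer(window)
    if (len < 1L || len > n) {
      stop(sprintf("window length %d outside record of %d tasks", len, n),
           call. = FALSE)
    }
    return((n - len + 1L):n)
  }
  idx <- as.integer(window)
  if (length(idx) == 0L || any(idx < 1L) || any(idx > n)) {
    stop("window positions must be inside the record", call. = FALSE)
  }
  idx
}

#' Each agent's share of initiations
#'
#' The fraction \eqn{p_i} of window tasks in which agent \eqn{i} was the
#' initiator. Every task has exactly one initiator, so shares sum to 1.
#'
#' @param record An `"evolution_record"` from [run_evolution()].
#' @param window Either a single integer (the length of the trailing window,
#'   default 100) or an integer vector of 1-based task positions.
#' @return Numeric vector of length \eqn{N} summing to 1.
#' @export
initiator_shares <- function(record, window = NULL) {
  stopifnot(inherits(record, "evolution_record"))
  if (record$variant != "personality") {
    stop("initiator shares are undefined for reference-model records",
         call. = FALSE)
  }
  idx <- resolve_window(record, window)
  n <- record$params$n_agents
  tabulate(record$tasks$initiator[idx], nbins = n) / length(idx)
}

#' Diversity index of initiator shares
#'
#' The population standard deviation of the shares,
#' \deqn{d_I = \sqrt{\frac{1}{N}\sum_i (p_i - \bar p)^2},}
#' a direct measure of how unevenly the initiator role is distributed (and so
#' of personality-trait diversity). It is 0 for uniform shares and attains
#' its maximum \eqn{\sqrt{N-1}/N} when one agent initiates every task.
#'
#' @param shares Numeric vector of nonnegative shares summing to 1.
#' @return The diversity index \eqn{d_I}.
#' @examples
#' diversity_index(rep(1 / 6, 6))       # 0
#' diversity_index(c(1, 0, 0, 0, 0, 0)) # sqrt(5)/6
#' @export
diversity_index <- function(shares) {
  if (!is.numeric(shares) || length(shares) == 0L || anyNA(shares)) {
    stop("shares must be a nonempty numeric vector", call. = FALSE)
  }
  sqrt(mean((shares - mean(shares))^2))
}

#' Windowed summary statistics of an evolution
#'
#' Computes the run-level statistics over a trailing window (default the last
#' 100 tasks, chosen to characterize the stabilized phase of a 200-task
#' evolution): mean boldness, mean bold and cooperator counts, the diversity
#' index of initiator shares, the mean winning decision time, per-capita
#' per-task cost \eqn{c\,n_C/N} and pay-off \eqn{\sum_i \pi_i / N}, and the
#' success rate. For reference-model records the initiator-based quantities
#' (`diversity`, `mean_decision_time`, `initiator_shares`) are `NA`.
#'
#' @inheritParams initiator_shares
#' @return A `"summary_stats"` list with fields `window` (range of 0-based
#'   task indices), `n_tasks`, `mean_trait`, `mean_n_bold`, `mean_n_coop`,
#'   `diversity`, `mean_decision_time`, `mean_cost`, `mean_payoff`,
#'   `success_rate`, `initiator_shares`.
#' @export
summarize_evolution <- function(record, window = NULL) {
  stopifnot(inherits(record, "evolution_record"))
  idx <- resolve_window(record, window)
  tk <- record$tasks[idx, , drop = FALSE]
  n <- record$params$n_agents
  trait_cols <- paste0("trait_", seq_len(n))
  payoff_cols <- paste0("payoff_", seq_len(n))
  personality <- record$variant == "personality"
  shares <- if (personality) initiator_shares(record, idx) else
    rep(NA_real_, n)
  structure(list(
    window = range(tk$task_index),
    n_tasks = nrow(tk),
    mean_trait = mean(as.matrix(tk[trait_cols])),
    mean_n_bold = mean(tk$n_bold),
    mean_n_coop = mean(tk$n_coop),
    diversity = if (personality) diversity_index(shares) else NA_real_,
    mean_decision_time = if (personality) mean(tk$decision_time) else NA_real_,
    mean_cost = mean(record$params$cost * tk$n_coop / n),
    mean_payoff = mean(rowSums(as.matrix(tk[payoff_cols])) / n),
    success_rate = mean(tk$outcome),
    initiator_shares = shares
  ), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("Summary over tasks %d-%d (%d tasks):\n",
              x$window[1], x$window[2], x$n_tasks))
  cat(sprintf("  success rate     %.3f\n", x$success_rate))
  cat(sprintf("  mean boldness    %.3f   bold agents %.2f\n",
              x$mean_trait, x$mean_n_bold))
  cat(sprintf("  cooperators n_C  %.2f   diversity d_I %.3f\n",
              x$mean_n_coop, x$diversity))
  cat(sprintf("  decision time    %.3f\n", x$mean_decision_time))
  cat(sprintf("  per-capita cost  %.3f   pay-off %.3f\n",
              x$mean_cost, x$mean_payoff))
  invisible(x)
}
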