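#' Obstacle difficulty levels
#'
#' Four difficulty levels, realized physically as obstacles of increasing
#' weight. `obstacle_weights()` returns the weights in kilograms.
#'
#' @return `obstacle_levels()`: character vector `c("O1","O2","O3","O4")` in
#'   ascending difficulty; `obstacle_weights()`: named numeric vector of
#'   weights (kg).
#' @export
obstacle_levels <- function() c("O1", "O2", "O3", "O4")

#' @rdname obstacle_levels
#' @export
obstacle_weights <- function() {
  c(O1 = 1.6, O2 = 2.0, O3 = 2.5, O4 = 2.9)
}

#' Construct a success-probability table
#'
#' The success model stands in for the physical environment: it maps
#' (obstacle level, number of cooperators) to the probability that the group
#' removes the obstacle. A single Bernoulli draw per task replaces the
#' duration-dependent physical push.
#'
#' @param probabilities Numeric matrix, rows named by obstacle level, columns
#'   corresponding to cooperator counts `1..ncol`.
#' @return A `"success_table"` object.
#' @seealso [default_success_table()], [validate_success_table()]
#' @export
success_table <- function(probabilities) {
  if (!is.matrix(probabilities) || is.null(rownames(probabilities))) {
    stop("probabilities must be a matrix with obstacle-level rownames",
         call. = FALSE)
  }
  if (anyNA(probabilities) || any(probabilities < 0) || any(probabilities > 1)) {
    stop("success probabilities must lie in [0, 1]", call. = FALSE)
  }
  colnames(probabilities) <- seq_len(ncol(probabilities))
  structure(list(probabilities = probabilities), class = "success_table")
}

#' Default success table
#'
#' Pinned empirical cells: a lone cooperator succeeds on O1 in 17% of tasks
#' and never on O2–O4; two cooperators always clear O1 but none of the
#' heavier obstacles; six cooperators always succeed. Unpinned cells use a
#' deterministic threshold fill — success probability 1 at or above
#' per-obstacle cooperator thresholds 2/3/4/5 for O1..O4 and 0 below — which
#' is consistent with the qualitative description of the environment and with
#' O4 succeeding almost surely at 5–6 cooperators. The fill is a declared
#' stand-in for the unpublished full empirical matrix; supply your own matrix
#' via [success_table()] to override it.
#'
#' @param n_agents Number of agents (table covers cooperator counts
#'   `1..n_agents`).
#' @return A `"success_table"`.
#' @examples
#' tab <- default_success_table(6)
#' success_probability(tab, "O1", 1)  # 0.17
#' @export
default_success_table <- function(n_agents = 6L) {
  stopifnot(n_agents >= 1)
  thresholds <- c(O1 = 2, O2 = 3, O3 = 4, O4 = 5)
  m <- t(vapply(thresholds, function(thr) {
    as.numeric(seq_len(n_agents) >= thr)
  }, numeric(n_agents)))
  rownames(m) <- names(thresholds)
  m["O1", 1] <- 0.17
  success_table(m)
}

#' Constant success table
#'
#' Every cell holds the same probability `p` — a forced environment, useful
#' for closed-form checks of the trait dynamics (e.g. `p = 1` makes every
#' task succeed).
#'
#' @param p Success probability applied to every (level, cooperator) cell.
#' @param n_agents Number of agents.
#' @param levels Obstacle labels to cover.
#' @return A `"success_table"`.
#' @export
constant_success_table <- function(p, n_agents = 6L, levels = obstacle_levels()) {
  m <- matrix(p, nrow = length(levels), ncol = n_agents,
              dimnames = list(levels, NULL))
  success_table(m)
}

#' Look up a success probability
#'
#' @param table A `"success_table"`.
#' @param obstacle Obstacle level label.
#' @param n_coop Number of cooperators (1..N).
#' @return The stored probability in \[0, 1\].
#' @export
success_probability <- function(table, obstacle, n_coop) {
  stopifnot(inherits(table, "success_table"))
  m <- table$probabilities
  if (!obstacle %in% rownames(m)) {
    stop(sprintf("success table does not cover obstacle '%s'", obstacle),
         call. = FALSE)
  }
  if (n_coop < 1 || n_coop > ncol(m) || n_coop != round(n_coop)) {
    stop(sprintf("cooperator count %s outside table domain 1..%d",
                 format(n_coop), ncol(m)), call. = FALSE)
  }
  m[obstacle, n_coop]
}

#' Draw a task outcome
#'
#' Bernoulli draw with the table probability. Deterministic (no RNG draw)
#' when the probability is exactly 0 or 1.
#'
#' @inheritParams success_probability
#' @return Integer 0 or 1.
#' @export
sample_outcome <- function(table, obstacle, n_coop) {
  p <- success_probability(table, obstacle, n_coop)
  if (p <= 0) return(0L)
  if (p >= 1) return(1L)
  as.integer(stats::runif(1L) < p)
}

#' Check the monotonicity invariants of a success table
#'
#' A physically sensible table is nondecreasing in the number of cooperators
#' (more pushers never hurt) and nonincreasing in obstacle difficulty for a
#' fixed cooperator count. Reports violations instead of throwing, so tables
#' loaded from configuration can surface every problem at once.
#'
#' @param table A `"success_table"`.
#' @return Character vector of violation messages; empty if the table is
#'   valid.
#' @export
validate_success_table <- function(table) {
  stopifnot(inherits(table, "success_table"))
  m <- table$probabilities
  out <- character()
  for (lvl in rownames(m)) {
    d <- diff(m[lvl, ])
    bad <- which(d < 0)
    for (j in bad) {
      out <- c(out, sprintf(
        "success must be nondecreasing in cooperators: (%s, n_C=%d) = %g > (%s, n_C=%d) = %g",
        lvl, j, m[lvl, j], lvl, j + 1L, m[lvl, j + 1L]))
    }
  }
  lv <- intersect(obstacle_levels(), rownames(m))
  if (length(lv) > 1L) {
    for (k in seq_len(length(lv) - 1L)) {
      worse <- which(m[lv[k + 1L], ] > m[lv[k], ])
      for (j in worse) {
        out <- c(out, sprintf(
          "success must be nonincreasing in difficulty: (%s, n_C=%d) = %g > (%s, n_C=%d) = %g",
          lv[k + 1L], j, m[lv[k + 1L], j], lv[k], j, m[lv[k], j]))
      }
    }
  }
  out
}

#' @export
print.success_table <- function(x, ...) {
  cat("Success-probability table (rows: obstacle level, cols: n_C):\n")
  print(x$probabilities)
  invisible(x)
}
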