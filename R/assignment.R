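#' Optimal one-to-one assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear sum assignment problem by the O(n^3)
#' augmenting-path (Jonker-Volgenant style potentials) formulation.
#' Deterministic: rows are processed in order, so among equal-cost optima
#' the solution found prefers earlier rows/columns.
#'
#' @param cost Numeric matrix of finite costs (rows = agents,
#'   columns = tasks). May be rectangular; `min(nrow, ncol)` pairs are
#'   assigned.
#' @return Integer vector of length `nrow(cost)`; element `i` is the
#'   column assigned to row `i`, or `NA` if the row is unassigned
#'   (only when `nrow > ncol`).
#' @export
hungarian_assign <- function(cost) {
  stopifnot(is.matrix(cost), all(is.finite(cost)))
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  transposed <- FALSE
  if (n > m) { cost <- t(cost); tmp <- n; n <- nrow(cost); m <- ncol(cost); transposed <- TRUE }
  # potentials over rows (u) and columns (v); way[j] = predecessor column
  INF <- Inf
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)  # p[j] = row matched to column j (0 = free)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    way <- integer(m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assign_row <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j] > 0L) assign_row[p[j]] <- j
  if (transposed) {
    out <- rep(NA_integer_, m)
    for (i in seq_len(n)) if (!is.na(assign_row[i])) out[assign_row[i]] <- i
    out
  } else assign_row
}

#' Gated minimum-cost assignment
#'
#' Maximum-cardinality, minimum-total-cost one-to-one matching restricted
#' to admissible pairs. Infeasible pairs (cost `Inf` or `feasible` FALSE)
#' can never be matched; among matchings of maximum cardinality over the
#' feasible pairs, the one with least total cost is returned. Implemented
#' by padding the cost matrix with a large constant and running
#' [hungarian_assign()], then stripping padded matches.
#'
#' @param cost Numeric matrix; `Inf` marks an inadmissible pair.
#' @param feasible Optional logical matrix, same shape; `FALSE` also marks
#'   a pair inadmissible.
#' @return A list with `matches` (two-column integer matrix `row`, `col`),
#'   `unmatched_rows`, `unmatched_cols`, and `total_cost`.
#' @export
gated_assignment <- function(cost, feasible = NULL) {
  n <- nrow(cost); m <- ncol(cost)
  if (is.null(feasible)) feasible <- matrix(TRUE, n, m)
  feasible <- feasible & is.finite(cost)
  empty <- list(matches = cbind(row = integer(0), col = integer(0)),
                unmatched_rows = seq_len(n), unmatched_cols = seq_len(m),
                total_cost = 0)
  if (n == 0L || m == 0L || !any(feasible)) return(empty)
  finite_vals <- cost[feasible]
  # BIG dominates any sum of real costs, so the solver first maximises the
  # number of feasible pairs, then minimises their total cost
  big <- sum(abs(finite_vals)) + max(abs(finite_vals)) + 1
  work <- matrix(big, n, m)
  work[feasible] <- cost[feasible]
  a <- hungarian_assign(work)
  rows <- which(!is.na(a))
  cols <- a[rows]
  keep <- feasible[cbind(rows, cols)]
  rows <- rows[keep]; cols <- cols[keep]
  list(matches = cbind(row = rows, col = cols),
       unmatched_rows = setdiff(seq_len(n), rows),
       unmatched_cols = setdiff(seq_len(m), cols),
       total_cost = if (length(rows)) sum(cost[cbind(rows, cols)]) else 0)
}

#' Greedy nearest-cost assignment
#'
#' Ablation alternative to [gated_assignment()]: repeatedly takes the
#' globally cheapest admissible pair. Not optimal in general.
#'
#' @inheritParams gated_assignment
#' @return Same structure as [gated_assignment()].
#' @export
greedy_assignment <- function(cost, feasible = NULL) {
  n <- nrow(cost); m <- ncol(cost)
  if (is.null(feasible)) feasible <- matrix(TRUE, n, m)
  feasible <- feasible & is.finite(cost)
  rows <- integer(0); cols <- integer(0)
  work <- cost
  work[!feasible] <- Inf
  while (any(is.finite(work))) {
    k <- which.min(work)
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    rows <- c(rows, i); cols <- c(cols, j)
    work[i, ] <- Inf; work[, j] <- Inf
  }
  list(matches = cbind(row = rows, col = cols),
       unmatched_rows = setdiff(seq_len(n), rows),
       unmatched_cols = setdiff(seq_len(m), cols),
       total_cost = if (length(rows)) sum(cost[cbind(rows, cols)]) else 0)
}
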