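# Optimal assignment for square cost matrices (Hungarian algorithm,
# shortest-augmenting-path formulation with dual potentials, O(n^3)).
# Deterministic: among equal-cost assignments the scan order (ascending
# column index) decides, so ties break toward the lowest index.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square", call. = FALSE)
  if (anyNA(cost) || any(!is.finite(cost))) stop("cost matrix must be finite", call. = FALSE)
  if (n == 1L) return(1L)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment
}
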