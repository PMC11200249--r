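# Minimum-cost assignment (Hungarian algorithm).
#
# Jonker-Volgenant style shortest-augmenting-path implementation with dual
# potentials, O(n^2 m).  Handles rectangular problems with nrow <= ncol
# directly (each row is assigned a distinct column); callers with more rows
# than columns transpose first.

#' Solve the minimum-cost assignment problem
#'
#' Finds the injection of rows into columns minimizing the total cost, for an
#' `n x m` cost matrix with `n <= m`.
#'
#' @param cost numeric cost matrix, `nrow(cost) <= ncol(cost)`, all finite.
#' @return `list(assignment=, total_cost=)`, where `assignment[i]` is the
#'   column matched to row i.
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost)) stopf("cost must be a matrix")
  if (any(!is.finite(cost))) stopf("cost matrix has non-finite entries")
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stopf("cost matrix needs nrow <= ncol (transpose first)")
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)              # row potentials (index n+1 = virtual row)
  v <- numeric(m + 1L)              # column potentials (index m+1 = virtual col)
  p <- integer(m + 1L)              # p[j] = row matched to column j (0 = none)
  way <- integer(m + 1L)
  VC <- m + 1L                      # virtual column index
  for (i in seq_len(n)) {
    p[VC] <- i
    j0 <- VC
    minv <- rep(INF, m)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      free <- which(!used[seq_len(m)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      k <- which.min(minv[free])
      delta <- minv[free[k]]
      j1 <- free[k]
      usedj <- which(used)
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == VC) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assignment[p[j]] <- j
  list(assignment = assignment,
       total_cost = sum(cost[cbind(seq_len(n), assignment)]))
}
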