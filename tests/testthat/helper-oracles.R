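# Brute-force oracles, kept independent of the implementation paths they
# check.

# All injections of 1..n into 1..m (n <= m).
all_injections <- function(n, m) {
  out <- list()
  rec <- function(prefix, used) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (j in setdiff(seq_len(m), used)) rec(c(prefix, j), c(used, j))
  }
  rec(integer(0), integer(0))
  out
}

# Exhaustive minimum-cost assignment.
brute_assignment <- function(C) {
  best <- Inf
  ba <- NULL
  for (p in all_injections(nrow(C), ncol(C))) {
    tc <- sum(C[cbind(seq_len(nrow(C)), p)])
    if (tc < best) {
      best <- tc
      ba <- p
    }
  }
  list(assignment = ba, total_cost = best)
}

# Wasserstein-1 between equal-size uniform empirical distributions by
# enumerating all permutation transport plans.
brute_w1_equal <- function(A, B) {
  D <- sqrt(softmsm:::cross_dist2(A, B))
  brute_assignment(D)$total_cost / nrow(A)
}

# Best per-model assignment of states to reference centers (exhaustive).
brute_best_assignment <- function(xi, centers) {
  D <- sqrt(softmsm:::cross_dist2(xi, centers))
  brute_assignment(D)$assignment
}

# Monte-Carlo mean first-passage times of a chain, vectorized over many
# walkers.
mc_mfpt <- function(T, from, to, n_walkers, seed, max_steps = 1e5) {
  K <- nrow(T)
  cum <- t(apply(T, 1, cumsum))
  withr::with_seed(seed, {
    state <- rep.int(from, n_walkers)
    steps <- numeric(n_walkers)
    active <- state != to
    k <- 0L
    while (any(active) && k < max_steps) {
      k <- k + 1L
      idx <- which(active)
      u <- stats::runif(length(idx))
      nxt <- integer(length(idx))
      for (s in unique(state[idx])) {
        sel <- state[idx] == s
        nxt[sel] <- pmin(K, findInterval(u[sel], cum[s, ],
                                         left.open = TRUE) + 1L)
      }
      state[idx] <- nxt
      steps[idx] <- steps[idx] + 1
      active[idx] <- nxt != to
    }
    mean(steps)
  })
}

# Area under the ROC curve of a score against binary labels.
auc_score <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
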