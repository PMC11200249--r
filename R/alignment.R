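# State alignment.
#
# Within a system, the N models of an ensemble are aligned by constrained
# k-means on their per-state average feature matrices (no two states of one
# model may share a cluster).  Across systems, each state is represented by
# the uniform empirical distribution of its per-model average feature
# matrices; states are compared by the Wasserstein-1 distance between those
# distributions and matched by the Hungarian algorithm, with a cost
# threshold T_e separating genuinely aligned states from unmatched ones.

#' Uniform empirical distribution of per-model state feature matrices
#'
#' @param atoms `N x F` matrix: one average feature vector per model.
#' @param system_label,state_label provenance labels.
#' @return an object of class `state_distribution` (uniform weights 1/N).
#' @export
state_distribution <- function(atoms, system_label = "", state_label = NA) {
  if (is.null(dim(atoms))) atoms <- base::matrix(atoms, nrow = 1)
  if (nrow(atoms) < 1) stopf("a state distribution needs at least one atom")
  structure(list(atoms = atoms, weights = rep(1 / nrow(atoms), nrow(atoms)),
                 system_label = system_label, state_label = state_label),
            class = "state_distribution")
}

#' Per-model per-state average feature matrices
#'
#' The average feature vector of state m under model n is the
#' soft-probability-weighted (or hard-membership) mean of the sampled frame
#' features, the quantity on which both alignment algorithms operate.
#'
#' @param models list of `soft_model`s (or a `model_ensemble`).
#' @param frames `n x F` matrix of sampled frames.
#' @param weighting `"soft"` (probability weights) or `"hard"` (argmax
#'   membership).
#' @param min_weight minimum total weight a state must collect.
#' @return list over models of `M x F` matrices (row m = state m's average).
#' @export
state_feature_matrices <- function(models, frames, weighting = c("soft", "hard"),
                                   min_weight = 1e-6) {
  weighting <- match.arg(weighting)
  if (inherits(models, "model_ensemble")) models <- models$models
  if (is.null(dim(frames)) || nrow(frames) < 1) {
    stopf("frames must be a non-empty matrix")
  }
  lapply(seq_along(models), function(n) {
    P <- predict_probs(models[[n]], frames)
    if (weighting == "hard") {
      lab <- max.col(P, ties.method = "first")
      P <- base::matrix(0, nrow(P), ncol(P))
      P[cbind(seq_len(nrow(P)), lab)] <- 1
    }
    w <- colSums(P)
    low <- which(w < min_weight)
    if (length(low)) {
      stopf("state %d of model %d has total weight %.3g < %g",
            low[1], n, w[low[1]], min_weight)
    }
    sweep(crossprod(P, frames), 1, w, `/`)
  })
}

# Squared Euclidean distances between rows of A and rows of B.  Computed
# from explicit differences: all callers pass small matrices (states x
# features), and the difference form is exact for coincident rows, which
# matters for the metric identity W(p, p) = 0.
cross_dist2 <- function(A, B) {
  D <- base::matrix(0, nrow(A), nrow(B))
  for (j in seq_len(nrow(B))) {
    d <- sweep(A, 2, B[j, ], `-`)
    D[, j] <- rowSums(d * d)
  }
  D
}

#' Align the states of an ensemble's models by constrained k-means
#'
#' Cluster centers are initialized from one model's state feature matrices.
#' Each iteration (1) assigns, per model, its states to distinct clusters
#' greedily in order of proximity (all state-center distances of the model
#' sorted ascending, ties broken by lower state then lower cluster index),
#' and (2) recomputes each center as the mean of its member matrices.
#' Iteration stops when assignments repeat (convergence or a cycle) or at
#' `max_iter`.
#'
#' @param xi_matrices list over models of `M x F` state feature matrices.
#' @param init_model index of the model initializing the centers, or
#'   `"random"` (seed-controlled).
#' @param seed used when `init_model = "random"`.
#' @param max_iter iteration cap.
#' @return an object of class `within_alignment` with `permutations` (per
#'   model, `perm[m]` = cluster of model-state m), `cluster_centers`,
#'   `n_iterations` and `converged`.
#' @export
align_within_system <- function(xi_matrices, init_model = "random", seed = 1,
                                max_iter = 100) {
  N <- length(xi_matrices)
  if (N == 0) stopf("no models to align")
  M <- nrow(xi_matrices[[1]])
  if (any(vapply(xi_matrices, nrow, integer(1)) != M)) {
    stopf("all models must have the same number of states")
  }
  if (identical(init_model, "random")) {
    init_model <- with_seed(seed, sample.int(N, 1))
  }
  centers <- xi_matrices[[init_model]]
  assign_tab <- base::matrix(0L, N, M)  # assign_tab[n, m] = cluster of state m
  history <- character(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (n in seq_len(N)) {
      D <- sqrt(cross_dist2(xi_matrices[[n]], centers))
      ord <- order(as.vector(D))  # column-major: ties -> lower state index
                                  # first (rows), then lower cluster index
      st_of <- ((ord - 1L) %% M) + 1L
      cl_of <- ((ord - 1L) %/% M) + 1L
      a <- integer(M)
      taken <- logical(M)
      done <- 0L
      for (k in seq_along(ord)) {
        s <- st_of[k]; cl <- cl_of[k]
        if (a[s] == 0L && !taken[cl]) {
          a[s] <- cl
          taken[cl] <- TRUE
          done <- done + 1L
          if (done == M) break
        }
      }
      stopifnot(!anyDuplicated(a))  # one state per model per cluster
      assign_tab[n, ] <- a
    }
    fp <- paste(assign_tab, collapse = ",")
    if (length(history) && fp == history[length(history)]) {
      converged <- TRUE
      break
    }
    if (fp %in% history) break  # cycle: stop without the converged flag
    history <- c(history, fp)
    for (cl in seq_len(M)) {
      members <- t(vapply(seq_len(N),
                          function(n) xi_matrices[[n]][which(assign_tab[n, ] == cl), ],
                          numeric(ncol(centers))))
      centers[cl, ] <- colMeans(members)
    }
  }
  structure(list(permutations = lapply(seq_len(N), function(n) assign_tab[n, ]),
                 cluster_centers = centers, n_iterations = iter,
                 converged = converged, init_model = init_model),
            class = "within_alignment")
}

#' @export
print.within_alignment <- function(x, ...) {
  cat(sprintf("within_alignment: %d models, %d clusters, %d iterations (%s)\n",
              length(x$permutations), nrow(x$cluster_centers), x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Wasserstein-1 distance between two uniform empirical distributions
#'
#' Euclidean ground cost.  The transportation linear program with uniform
#' marginals over N1 and N2 atoms is solved exactly by replicating each atom
#' to lcm(N1, N2) copies and solving the resulting assignment problem (an
#' optimal vertex of the uniform transportation polytope is a permutation
#' matrix, so the reduction is exact).
#'
#' @param p,q [state_distribution()]s (or plain atom matrices).
#' @return the Wasserstein-1 distance.
#' @export
wasserstein1 <- function(p, q) {
  A <- if (inherits(p, "state_distribution")) p$atoms else
    if (is.null(dim(p))) base::matrix(p, ncol = 1) else p
  B <- if (inherits(q, "state_distribution")) q$atoms else
    if (is.null(dim(q))) base::matrix(q, ncol = 1) else q
  if (ncol(A) != ncol(B)) {
    stopf("feature dimensions differ (%d vs %d)", ncol(A), ncol(B))
  }
  n1 <- nrow(A); n2 <- nrow(B)
  g <- gcd_int(n1, n2)
  L <- n1 / g * n2
  ia <- rep(seq_len(n1), each = L / n1)
  ib <- rep(seq_len(n2), each = L / n2)
  D <- sqrt(cross_dist2(A, B))[ia, ib, drop = FALSE]
  solve_assignment(D)$total_cost / L
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Cross-system Wasserstein-1 cost matrix
#'
#' @param system1_distributions,system2_distributions lists of
#'   [state_distribution()]s (one per state).
#' @return `M1 x M2` matrix; entry (m, l) is the Wasserstein-1 distance
#'   between state m of system 1 and state l of system 2.
#' @export
cost_matrix <- function(system1_distributions, system2_distributions) {
  M1 <- length(system1_distributions)
  M2 <- length(system2_distributions)
  C <- base::matrix(NA_real_, M1, M2)
  for (m in seq_len(M1)) {
    for (l in seq_len(M2)) {
      C[m, l] <- wasserstein1(system1_distributions[[m]],
                              system2_distributions[[l]])
    }
  }
  C
}

#' Match states across two systems
#'
#' Finds the bijection from the states of the smaller system into the states
#' of the larger minimizing the total Wasserstein-1 cost (Hungarian
#' algorithm), then flags each matched pair as genuinely aligned when its
#' cost falls below the threshold T_e.
#'
#' @param cost `M1 x M2` cost matrix from [cost_matrix()].
#' @param threshold alignment-cost threshold T_e (default 6, feature-space
#'   units, Angstrom).
#' @return an object of class `cross_alignment`: `mapping[m]` is the state
#'   of the larger system matched to state m of the smaller, `matched[m]`
#'   whether the pair's cost is below threshold, `swapped` whether the input
#'   systems were reordered so that system 1 is the smaller.
#' @export
align_across_systems <- function(cost, threshold = 6) {
  if (!is.matrix(cost)) stopf("cost must be a matrix")
  if (any(!is.finite(cost))) stopf("cost matrix has non-finite entries")
  swapped <- nrow(cost) > ncol(cost)
  C <- if (swapped) t(cost) else cost
  sol <- solve_assignment(C)
  costs <- C[cbind(seq_len(nrow(C)), sol$assignment)]
  structure(list(cost = cost, mapping = sol$assignment,
                 pair_costs = costs, total_cost = sol$total_cost,
                 threshold = threshold, matched = costs < threshold,
                 swapped = swapped),
            class = "cross_alignment")
}

#' @export
print.cross_alignment <- function(x, ...) {
  dir <- if (x$swapped) "system 2 -> system 1" else "system 1 -> system 2"
  cat(sprintf("cross_alignment (%s), total cost %.4g, threshold T_e = %g\n",
              dir, x$total_cost, x$threshold))
  for (m in seq_along(x$mapping)) {
    cat(sprintf("  state %d -> state %d  cost %.4g  %s\n", m, x$mapping[m],
                x$pair_costs[m],
                if (x$matched[m]) "matched" else "unmatched"))
  }
  invisible(x)
}
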