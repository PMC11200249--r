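# Wasserstein-1 distances, cost matrices, and both alignment algorithms.

test_that("wasserstein1 reproduces hand-computable transports", {
  A <- matrix(c(0, 1, 2), 3, 1)
  expect_equal(wasserstein1(A, A), 0)
  expect_equal(wasserstein1(A, A + 1), 1)  # shift every atom by 1
  a <- matrix(c(1, 2, 3), 1, 3)
  b <- matrix(c(4, 6, 3), 1, 3)
  expect_equal(wasserstein1(a, b), sqrt(sum((a - b)^2)))  # single atoms
  expect_error(wasserstein1(matrix(0, 2, 3), matrix(0, 2, 4)),
               "dimensions differ")
})

test_that("wasserstein1 equals the permutation oracle for equal sizes", {
  set.seed(5)
  for (r in 1:40) {
    N <- sample(2:6, 1)
    d <- sample(1:5, 1)
    A <- matrix(rnorm(N * d, sd = 3), N, d)
    B <- matrix(rnorm(N * d, sd = 3), N, d)
    expect_equal(wasserstein1(A, B), brute_w1_equal(A, B), tolerance = 1e-9)
  }
})

test_that("wasserstein1 behaves as a metric on random triples", {
  set.seed(6)
  for (r in 1:25) {
    d <- sample(1:5, 1)
    P <- lapply(1:3, function(i) matrix(rnorm(sample(1:4, 1) * d), ncol = d))
    w12 <- wasserstein1(P[[1]], P[[2]])
    w13 <- wasserstein1(P[[1]], P[[3]])
    w23 <- wasserstein1(P[[2]], P[[3]])
    expect_gte(w12, 0)
    expect_equal(w12, wasserstein1(P[[2]], P[[1]]), tolerance = 1e-9)
    expect_lte(w13, w12 + w23 + 1e-9)
    expect_equal(wasserstein1(P[[1]], P[[1]]), 0, tolerance = 1e-12)
  }
})

test_that("cost matrices are symmetric across system order and zero on self", {
  set.seed(7)
  dists1 <- lapply(1:3, function(m) state_distribution(matrix(rnorm(12), 4, 3)))
  dists2 <- lapply(1:2, function(m) state_distribution(matrix(rnorm(12), 4, 3)))
  C12 <- cost_matrix(dists1, dists2)
  C21 <- cost_matrix(dists2, dists1)
  expect_equal(C12, t(C21), tolerance = 1e-9)
  Cself <- cost_matrix(dists1, dists1)
  expect_equal(diag(Cself), rep(0, 3), tolerance = 1e-12)
  for (m in 1:3) for (l in 1:2) {
    expect_equal(C12[m, l],
                 brute_w1_equal(dists1[[m]]$atoms, dists2[[l]]$atoms),
                 tolerance = 1e-9)
  }
})

test_that("cross-system matching minimizes total cost and applies T_e", {
  al <- align_across_systems(matrix(c(0, 5, 5, 0), 2, 2), threshold = 6)
  expect_equal(al$mapping, c(1L, 2L))
  expect_equal(al$total_cost, 0)
  expect_true(all(al$matched))
  # 2 states into 3, matches exhaustive enumeration of all 6 injections
  C <- matrix(c(4, 2, 7, 6, 1, 5), 2, 3)
  al2 <- align_across_systems(C, threshold = 6)
  expect_equal(al2$mapping, c(3L, 1L))
  expect_equal(al2$total_cost, brute_assignment(C)$total_cost)
  expect_equal(al2$total_cost, 3)
  # all costs above threshold: mapping still valid, nothing matched
  al3 <- align_across_systems(C + 100, threshold = 6)
  expect_equal(al3$mapping, al2$mapping)
  expect_false(any(al3$matched))
  # wider first system is swapped internally
  al4 <- align_across_systems(t(C), threshold = 6)
  expect_true(al4$swapped)
  expect_equal(al4$total_cost, 3)
})

test_that("hungarian agrees with enumeration on random cross-system costs", {
  set.seed(8)
  for (r in 1:40) {
    M1 <- sample(2:4, 1)
    M2 <- M1 + sample(0:2, 1)
    C <- matrix(runif(M1 * M2, 0, 12), M1, M2)
    al <- align_across_systems(C, threshold = 6)
    want <- brute_assignment(C)
    expect_equal(al$total_cost, want$total_cost, tolerance = 1e-9)
  }
})

test_that("state feature matrices are probability-weighted frame means", {
  set.seed(9)
  frames <- matrix(runif(200 * 6, 0, 10), 200, 6)
  one_state <- function(f) matrix(1, nrow(f), 1)
  xi <- state_feature_matrices(list(one_state), frames)
  expect_equal(xi[[1]][1, ], colMeans(frames))
  uniform <- function(f) matrix(1 / 3, nrow(f), 3)
  xi_u <- state_feature_matrices(list(uniform), frames)
  for (m in 1:3) expect_equal(xi_u[[1]][m, ], colMeans(frames))
  # hard weighting uses argmax membership
  two_groups <- function(f) cbind(f[, 1] < 5, f[, 1] >= 5) * 1
  xi_h <- state_feature_matrices(list(two_groups), frames, weighting = "hard")
  expect_equal(xi_h[[1]][1, ], colMeans(frames[frames[, 1] < 5, ]))
  # zero-weight state errors with its identity
  all_first <- function(f) cbind(1, 0, 0)[rep(1, nrow(f)), ]
  expect_error(state_feature_matrices(list(all_first), frames),
               "state 2 of model 1")
})

test_that("state feature matrices recover generator emission means", {
  fx <- small_fixture()
  spec <- fx$spec
  xi <- state_feature_matrices(list(bayes_model(spec)),
                               softmsm:::dataset_matrix(fx$dataset))
  D <- sqrt(softmsm:::cross_dist2(xi[[1]], spec$emission_means))
  # each recovered state mean sits near exactly one generator mean
  expect_lt(max(apply(D, 1, min)), 0.5)
  expect_setequal(apply(D, 1, which.min), 1:3)
})

test_that("constrained k-means recovers permuted exact copies in one pass", {
  set.seed(10)
  ref <- matrix(runif(3 * 8, 0, 10), 3, 8)
  perms <- list(c(2, 3, 1), c(1, 2, 3), c(3, 1, 2), c(2, 1, 3))
  xi <- lapply(perms, function(p) ref[order(p), , drop = FALSE])
  wa <- align_within_system(xi, init_model = 2, max_iter = 50)
  expect_true(wa$converged)
  for (n in seq_along(perms)) {
    # model n's state s holds ref row perms-inverse; cluster labels must
    # undo the shuffle so that every cluster collects one copy of ref row
    got <- xi[[n]][order(wa$permutations[[n]]), ]
    expect_equal(got, wa$cluster_centers, tolerance = 1e-12)
  }
  expect_equal(wa$cluster_centers, ref[order(wa$permutations[[2]]), ],
               tolerance = 1e-12)
})

test_that("a single model aligns to itself immediately", {
  xi <- list(matrix(1:12, 3, 4))
  wa <- align_within_system(xi, init_model = 1)
  expect_equal(wa$permutations[[1]], 1:3)
  expect_true(wa$converged)
})

test_that("noisy copies are aligned like the exhaustive oracle", {
  set.seed(11)
  base_centers <- matrix(runif(3 * 10, 0, 10), 3, 10)
  sep <- min(dist(base_centers))
  for (seed in 1:10) {
    set.seed(seed + 100)
    perms <- lapply(1:5, function(n) sample.int(3))
    xi <- lapply(perms, function(p) {
      base_centers[order(p), ] + matrix(rnorm(30, sd = 0.1 * sep), 3, 10)
    })
    wa <- align_within_system(xi, init_model = "random", seed = seed)
    # cluster labels must be a relabeling of the generating permutations:
    # states generated from the same base row always share a cluster
    lab_of_base <- matrix(NA_integer_, 5, 3)
    for (n in 1:5) {
      for (s in 1:3) {
        base_row <- order(perms[[n]])[s]  # base row behind state s
        lab_of_base[n, base_row] <- wa$permutations[[n]][s]
      }
    }
    expect_true(all(apply(lab_of_base, 2, function(col) length(unique(col)) == 1)))
    # and each model's assignment matches its own exhaustive best fit
    for (n in 1:5) {
      expect_equal(wa$permutations[[n]],
                   brute_best_assignment(xi[[n]], wa$cluster_centers))
    }
  }
})

test_that("the one-state-per-cluster constraint is never violated", {
  set.seed(12)
  xi <- lapply(1:6, function(n) matrix(runif(4 * 5), 4, 5))
  wa <- align_within_system(xi, seed = 2, max_iter = 30)
  for (p in wa$permutations) expect_setequal(p, 1:4)
})
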