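# Variational scoring, training, and ensemble assignment.

test_that("a constant one-state model scores exactly 1", {
  set.seed(20)
  ds <- trajectory_dataset(list(matrix(runif(500 * 4), 500, 4)))
  pairs <- make_frame_pairs(ds, 2)
  const_model <- function(f) matrix(1, nrow(f), 1)
  expect_equal(vamp_e_score(const_model, pairs), 1.0, tolerance = 1e-12)
})

test_that("a perfect indicator model approaches 1 + lambda2^2 on a 2-state chain", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  s <- simulate_chain(T, 2e5, seed = 31)
  # features are the state labels themselves; the model reads them off
  ds <- trajectory_dataset(list(matrix(as.numeric(s), ncol = 1)))
  pairs <- make_frame_pairs(ds, 1)
  indicator <- function(f) cbind(f[, 1] == 1, f[, 1] == 2) * 1
  score <- vamp_e_score(indicator, pairs)
  expect_equal(score, 1 + 0.7^2, tolerance = 0.02)  # lambda2 = 0.7
  # relabeling the output states leaves the score unchanged
  flipped <- function(f) cbind(f[, 1] == 2, f[, 1] == 1) * 1
  expect_equal(vamp_e_score(flipped, pairs), score, tolerance = 1e-12)
})

test_that("scoring fails gracefully with fewer pairs than states", {
  ds <- trajectory_dataset(list(matrix(runif(8), 4, 2)))
  pairs <- make_frame_pairs(ds, 1)
  wide <- function(f) matrix(1 / 5, nrow(f), 5)
  expect_error(vamp_e_score(wide, pairs), "singular")
})

test_that("model outputs live on the probability simplex for any input", {
  m <- random_model(F = 10, M = 4, seed = 5)
  set.seed(6)
  X <- rbind(matrix(rnorm(200 * 10, sd = 3), 200, 10),
             matrix(1e6, 5, 10), matrix(-1e6, 5, 10))
  P <- predict(m, X)
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-10)
})

test_that("training is deterministic given seed and config", {
  fx <- small_fixture()
  pairs <- make_frame_pairs(fx$dataset, 5)
  sp <- split_pairs(pairs, n_splits = 1, seed = 3)
  cfg <- tiny_net_config(epochs = 6)
  m1 <- suppressWarnings(train_model(sp[[1]]$train, sp[[1]]$validation, 3,
                                     cfg, seed = 17))
  m2 <- suppressWarnings(train_model(sp[[1]]$train, sp[[1]]$validation, 3,
                                     cfg, seed = 17))
  expect_identical(m1$validation_vamp_e, m2$validation_vamp_e)
  expect_identical(m1$W, m2$W)
  m3 <- suppressWarnings(train_model(sp[[1]]$train, sp[[1]]$validation, 3,
                                     cfg, seed = 18))
  expect_false(identical(m1$validation_vamp_e, m3$validation_vamp_e))
})

test_that("a trained model recovers the hidden states of the fixture", {
  fx <- small_fixture()
  m <- small_trained_model()
  expect_gt(m$validation_vamp_e, 1)
  P <- predict(m, softmsm:::dataset_matrix(fx$dataset))
  lab <- max.col(P, ties.method = "first")
  truth <- unlist(fx$truth$labels)
  acc <- max(vapply(all_injections(3, 3), function(p) mean(p[lab] == truth),
                    numeric(1)))
  expect_gt(acc, 0.9)
})

test_that("validation VAMP-E increases with the true state count", {
  fx <- small_fixture()
  pairs <- make_frame_pairs(fx$dataset, 5)
  sp <- split_pairs(pairs, n_splits = 1, seed = 23)
  score_for_M <- function(M) {
    max(vapply(1:2, function(k) {
      suppressWarnings(train_model(sp[[1]]$train, sp[[1]]$validation, M,
                                   tiny_net_config(),
                                   seed = 400 + k))$validation_vamp_e
    }, numeric(1)))
  }
  expect_lt(score_for_M(2), score_for_M(3))
})

test_that("labels are invariant to a feature rescaling absorbed upstream", {
  fx <- small_fixture()
  sub <- trajectory_dataset(lapply(fx$dataset$trajectories[1:2],
                                   function(t) t[1:800, ]))
  sub10 <- trajectory_dataset(lapply(sub$trajectories, function(t) t * 10))
  cfg <- tiny_net_config(epochs = 10)
  lab <- lapply(list(sub, sub10), function(ds) {
    pairs <- make_frame_pairs(ds, 5)
    sp <- split_pairs(pairs, n_splits = 1, seed = 3)
    m <- suppressWarnings(train_model(sp[[1]]$train, sp[[1]]$validation, 3,
                                      cfg, seed = 19))
    max.col(predict(m, softmsm:::dataset_matrix(ds)), ties.method = "first")
  })
  expect_identical(lab[[1]], lab[[2]])
})

test_that("ensembles of identical models reproduce the single model", {
  m <- random_model(F = 6, M = 3, seed = 8)
  ens <- fake_ensemble(list(m, m, m))
  set.seed(9)
  X <- matrix(rnorm(50 * 6), 50, 6)
  expect_equal(soft_assign(ens, X), predict(m, X), tolerance = 1e-12)
})

test_that("soft assignments are simplex points and hard ties break low", {
  m1 <- random_model(F = 6, M = 3, seed = 10)
  m2 <- random_model(F = 6, M = 3, seed = 11)
  ens <- fake_ensemble(list(m1, m2))
  set.seed(12)
  X <- matrix(rnorm(1000 * 6, sd = 2), 1000, 6)
  P <- soft_assign(ens, X)
  expect_equal(rowSums(P), rep(1, 1000), tolerance = 1e-10)
  # documented tie rule: exact tie goes to the lowest state index
  tie <- function(f) matrix(c(0.5, 0.5), nrow(f), 2, byrow = TRUE)
  ens_tie <- fake_ensemble(list(tie), M = 2,
                           perms = list(1:2))
  expect_equal(hard_assign(ens_tie, X[1:5, ]), rep(1L, 5))
  expect_equal(max.col(matrix(c(0.2, 0.7, 0.1), 1), ties.method = "first"), 2)
})

test_that("unaligned ensembles refuse soft assignment", {
  m <- random_model(F = 6, M = 3, seed = 13)
  ens <- fake_ensemble(list(m))
  ens$state_permutations <- NULL
  expect_error(soft_assign(ens, matrix(0, 1, 6)), "align")
})

test_that("permutation correction reorders ensemble outputs", {
  m <- random_model(F = 6, M = 3, seed = 14)
  set.seed(15)
  X <- matrix(rnorm(20 * 6), 20, 6)
  perm <- c(3L, 1L, 2L)  # model state s belongs to cluster perm[s]
  ens <- fake_ensemble(list(m), perms = list(perm))
  P_raw <- predict(m, X)
  P_al <- soft_assign(ens, X)
  for (s in 1:3) expect_equal(P_al[, perm[s]], P_raw[, s])
})

test_that("small ensembles train reproducibly and keep the best init", {
  fx <- small_fixture()
  sub <- trajectory_dataset(fx$dataset$trajectories[1:2])
  cfg <- tiny_net_config(epochs = 8)
  ens1 <- suppressWarnings(train_ensemble(sub, M = 3, lag_steps = 5, N = 2,
                                          inits_per_split = 2, config = cfg,
                                          seed = 5))
  ens2 <- suppressWarnings(train_ensemble(sub, M = 3, lag_steps = 5, N = 2,
                                          inits_per_split = 2, config = cfg,
                                          seed = 5))
  v1 <- vapply(ens1$models, `[[`, numeric(1), "validation_vamp_e")
  v2 <- vapply(ens2$models, `[[`, numeric(1), "validation_vamp_e")
  expect_identical(v1, v2)
  # the retained model of each split carries its row's maximum score
  expect_equal(v1, apply(ens1$candidate_scores, 1, max))
  expect_equal(dim(ens1$candidate_scores), c(2L, 2L))
  for (p in ens1$state_permutations) expect_setequal(p, 1:3)
})
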