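# Koopman estimation, stationary laws, MFPTs, timescales, CK tests.

chain_dataset <- function(T, n, seed, lag_noise = 0.05) {
  s <- simulate_chain(T, n, seed)
  # one-hot features with slight jitter so covariances are well conditioned
  X <- one_hot(s, nrow(T)) + matrix(rnorm(n * nrow(T), sd = lag_noise),
                                    n, nrow(T))
  list(dataset = trajectory_dataset(list(X)), labels = s)
}

indicator_model <- function(K) {
  function(f) one_hot(max.col(f, ties.method = "first"), K)
}

test_that("equilibrium distributions solve classic chains", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_equal(equilibrium_distribution(T), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  D <- matrix(c(0.5, 0.3, 0.2,
                0.2, 0.5, 0.3,
                0.3, 0.2, 0.5), 3, 3, byrow = TRUE)  # doubly stochastic
  expect_equal(equilibrium_distribution(D), rep(1 / 3, 3), tolerance = 1e-12)
  for (eps in c(0.3, 1e-3, 1e-7)) {
    Te <- matrix(c(1 - eps, eps, eps, 1 - eps), 2, 2)
    expect_equal(equilibrium_distribution(Te), c(0.5, 0.5), tolerance = 1e-9)
  }
  expect_error(equilibrium_distribution(diag(2)), "reducible")
})

test_that("koopman estimation recovers the generating matrix from counts", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  cd <- chain_dataset(T, 1e5 + 1, seed = 41)
  pairs <- make_frame_pairs(cd$dataset, 1)
  est <- estimate_koopman(indicator_model(2), pairs)
  expect_lt(max(abs(est$T - T)), 0.02)
  expect_equal(rowSums(est$T), c(1, 1), tolerance = 1e-9)
  # detailed balance within tight tolerance in constrained mode
  flux <- est$pi * est$T
  expect_lt(max(abs(flux - t(flux))), 1e-8)
  expect_equal(est$pi, c(2 / 3, 1 / 3), tolerance = 0.02)
})

test_that("a symmetric two-well chain has a uniform stationary law", {
  T <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  cd <- chain_dataset(T, 4e4, seed = 42)
  est <- estimate_koopman(indicator_model(2),
                          make_frame_pairs(cd$dataset, 1))
  expect_equal(est$pi, c(0.5, 0.5), tolerance = 0.03)
})

test_that("unvisited states are reported by name", {
  ds <- trajectory_dataset(list(matrix(c(rep(1, 50), rep(0, 50)), 50, 2)))
  pairs <- make_frame_pairs(ds, 1)
  expect_error(estimate_koopman(function(f) cbind(1, 0, 0)[rep(1, nrow(f)), ],
                                pairs),
               "state 2")
})

test_that("mean first-passage times solve the geometric case exactly", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  mf <- mean_first_passage_times(T, lag_time = 25)
  expect_equal(diag(mf), c(0, 0))
  expect_equal(mf[1, 2], 25 / 0.1)  # geometric waiting time 1/a steps
  expect_equal(mf[2, 1], 25 / 0.2)
  expect_error(mean_first_passage_times(diag(2), 1), "singular")
})

test_that("mfpt agrees with a Monte-Carlo first-passage oracle", {
  T3 <- matrix(c(0.7, 0.2, 0.1,
                 0.2, 0.6, 0.2,
                 0.1, 0.3, 0.6), 3, 3, byrow = TRUE)
  mf <- mean_first_passage_times(T3, lag_time = 1)
  for (pair in list(c(1, 3), c(3, 1), c(2, 3))) {
    mc <- mc_mfpt(T3, pair[1], pair[2], n_walkers = 2e5,
                  seed = 50 + pair[1] * 3 + pair[2])
    expect_equal(mf[pair[1], pair[2]], mc, tolerance = 0.02)
  }
})

test_that("implied timescales match the closed form and are stable in tau", {
  T <- matrix(c(0.85, 0.15, 0.15, 0.85), 2, 2)  # lambda2 = 0.7
  n <- 2e5
  cd <- chain_dataset(T, n, seed = 43)
  lags <- c(1, 2, 4)
  models <- setNames(replicate(3, indicator_model(2), simplify = FALSE),
                     lags)
  pairs <- setNames(lapply(lags, function(l) {
    p <- make_frame_pairs(cd$dataset, l)
    p$frame_interval <- 25  # pretend frames are 25 ns apart
    p
  }), lags)
  its <- implied_timescales(models, pairs)
  t2_tab <- its[its$process == 2, ]
  # closed form at the base lag: -tau / ln(0.7) with tau = 25 ns
  expect_equal(t2_tab$timescale[t2_tab$lag_steps == 1], -25 / log(0.7),
               tolerance = 0.05)
  # Markovian data: flat in tau within sampling tolerance
  expect_lt(diff(range(t2_tab$timescale)) / mean(t2_tab$timescale), 0.15)
  expect_error(implied_timescales(models[1], pairs[1]), "at least 2")
})

test_that("implied timescales are invariant under state relabeling", {
  T3 <- matrix(c(0.8, 0.15, 0.05,
                 0.1, 0.8, 0.1,
                 0.05, 0.15, 0.8), 3, 3, byrow = TRUE)
  cd <- chain_dataset(T3, 5e4, seed = 44)
  lags <- c(1, 2)
  relabel <- function(f) indicator_model(3)(f)[, c(3, 1, 2)]
  p <- setNames(lapply(lags, function(l) make_frame_pairs(cd$dataset, l)),
                lags)
  its1 <- implied_timescales(setNames(replicate(2, indicator_model(3),
                                                simplify = FALSE), lags), p)
  its2 <- implied_timescales(setNames(replicate(2, relabel,
                                                simplify = FALSE), lags), p)
  expect_equal(its1$timescale, its2$timescale, tolerance = 1e-8)
  # ordering: process 2 is never faster than process 3
  for (lg in lags) {
    sub <- its1[its1$lag_steps == lg, ]
    expect_gte(sub$timescale[sub$process == 2],
               sub$timescale[sub$process == 3])
  }
})

test_that("chapman-kolmogorov holds on Markov data and flags memory", {
  T3 <- matrix(c(0.9, 0.07, 0.03,
                 0.1, 0.85, 0.05,
                 0.05, 0.1, 0.85), 3, 3, byrow = TRUE)
  cd <- chain_dataset(T3, 1e5, seed = 45)
  ck <- chapman_kolmogorov(indicator_model(3), cd$dataset, lag_steps = 1,
                           k_max = 5)
  expect_equal(ck$discrepancy[1], 0, tolerance = 1e-9)  # k = 1 by construction
  expect_lt(max(ck$discrepancy), 0.03)
  # a second-order (lag-2 dependent) chain violates CK increasingly with k
  set.seed(46)
  n <- 6e4
  s <- integer(n)
  s[1:2] <- c(1L, 2L)
  for (t in 3:n) {
    s[t] <- if (runif(1) < 0.9) s[t - 2] else sample.int(3, 1)
  }
  X <- one_hot(s, 3) + matrix(rnorm(n * 3, sd = 0.05), n, 3)
  ds2 <- trajectory_dataset(list(X))
  ck2 <- chapman_kolmogorov(indicator_model(3), ds2, lag_steps = 1, k_max = 4)
  expect_gt(max(ck2$discrepancy[-1]), ck2$discrepancy[1] + 0.02)
})

test_that("ensemble kinetic bands collapse for identical models", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  cd <- chain_dataset(T, 3e4, seed = 47)
  pairs <- make_frame_pairs(cd$dataset, 1)
  m <- indicator_model(2)
  ens <- fake_ensemble(list(m, m, m, m), M = 2,
                       perms = replicate(4, 1:2, simplify = FALSE))
  ks <- kinetics_summary(ens, pairs)
  expect_equal(ks$pi["2.5%", ], ks$pi["97.5%", ], tolerance = 1e-12)
  # duplicating every model leaves the median summaries unchanged
  ens2 <- fake_ensemble(rep(list(m), 8), M = 2,
                        perms = replicate(8, 1:2, simplify = FALSE))
  ks2 <- kinetics_summary(ens2, pairs)
  expect_equal(ks$pi["50%", ], ks2$pi["50%", ], tolerance = 1e-12)
  expect_equal(ks$mfpt, ks2$mfpt, tolerance = 1e-12)
})

test_that("stationarity of the estimate holds to numerical precision", {
  fx <- small_fixture()
  est <- estimate_koopman(bayes_model(fx$spec),
                          make_frame_pairs(fx$dataset, 5))
  expect_equal(as.numeric(est$pi %*% est$T), est$pi, tolerance = 1e-10)
  expect_equal(sum(est$pi), 1, tolerance = 1e-12)
  expect_true(all(est$T >= 0))
  # the Bayes-classifier MSM recovers the generator stationary law
  expect_lt(max(abs(est$pi - fx$truth$stationary)), 0.05)
})
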