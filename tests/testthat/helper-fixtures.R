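# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; expensive objects are memoized per run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Small realization of the canonical fixture (2 x 2500 frames) for cheap
# closed-loop unit tests; the acceptance tests use the full-size fixture.
small_fixture <- function() memo("small_fixture", {
  spec <- default_fixture(n_trajectories = 4, frames_per_trajectory = 2500,
                          seed = 7)
  c(generate_hmm_dataset(spec), list(spec = spec))
})

tiny_net_config <- function(epochs = 60, ...) {
  net_config(hidden = 32, epochs = epochs, batch_size = 1024, lr = 2e-3,
             patience = 15, ...)
}

# One trained model on the small fixture, reused across modules.
small_trained_model <- function() memo("small_trained_model", {
  fx <- small_fixture()
  pairs <- make_frame_pairs(fx$dataset, 5)
  sp <- split_pairs(pairs, n_splits = 1, seed = 3)
  suppressWarnings(train_model(sp[[1]]$train, sp[[1]]$validation, M = 3,
                               config = tiny_net_config(), seed = 11))
})

# A soft model with random (untrained) weights: gradient and simplex
# contracts are architecture-level properties.
random_model <- function(F = 45, M = 3, hidden = c(16, 16), seed = 1,
                         sd_scale = 1) {
  net <- softmsm:::net_init(c(F, hidden, M), seed)
  if (sd_scale != 1) net$W <- lapply(net$W, `*`, sd_scale)
  structure(list(W = net$W, b = net$b, dims = net$dims, M = M,
                 lag_steps = 1L, frame_interval = 0.1,
                 standardizer = list(mean = rep(8, F), sd = rep(2, F)),
                 validation_vamp_e = NA_real_, init_seed = seed,
                 config = net_config(hidden = hidden), low_score = FALSE),
            class = "soft_model")
}

# Wrap model-like objects (soft models or closures) into an aligned ensemble.
fake_ensemble <- function(models, perms = NULL, M = 3, xi = NULL) {
  perms <- perms %||% replicate(length(models), seq_len(M), simplify = FALSE)
  structure(list(models = models, state_permutations = perms,
                 state_feature_matrices = xi, M = M, lag_steps = 5L,
                 frame_interval = 0.1, system_label = "fake", seed = 1L),
            class = "model_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bayes classifier of a synthetic spec as a closure model.
bayes_model <- function(spec, prior = NULL) {
  force(spec); force(prior)
  function(frames) bayes_posteriors(frames, spec$emission_means, spec$sigma,
                                    prior = prior)
}

# Simulate a plain Markov chain over K states; returns integer labels.
simulate_chain <- function(T, n, seed, init = NULL) {
  K <- nrow(T)
  pi0 <- init %||% softmsm:::stationary_distribution(T)
  cum <- t(apply(T, 1, cumsum))
  withr::with_seed(seed, {
    s <- integer(n)
    s[1] <- sample.int(K, 1, prob = pi0)
    u <- stats::runif(n)
    for (t in 2:n) s[t] <- min(K, findInterval(u[t], cum[s[t - 1], ],
                                               left.open = TRUE) + 1L)
    s
  })
}

# One-hot rows.
one_hot <- function(labels, K) {
  P <- matrix(0, length(labels), K)
  P[cbind(seq_along(labels), labels)] <- 1
  P
}
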