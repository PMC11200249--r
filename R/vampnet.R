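# Soft Markov state models learned by variational scoring.
#
# A soft model is a nonlinear map from a feature vector to an M-state
# probability simplex, trained on time-lagged frame pairs by gradient ascent
# on the VAMP-E score of its output covariances.  An ensemble holds N such
# models (one per random 90/10 split, each the best of several
# initializations by validation VAMP-E), aligned to a common state order.

#' Training configuration for soft models
#'
#' @param hidden integer vector of hidden-layer widths (SELU activations).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size (pairs per step).
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation VAMP-E (epochs).
#' @param ridge relative diagonal regularization of the output covariances
#'   during training.  Besides numerical stabilization, the ridge resolves
#'   the mixing degeneracy of the variational score (which is invariant to
#'   invertible linear recombinations of the output states) in favor of
#'   maximum-variance, i.e. crisp, state assignments.
#' @param train_fraction fraction of pairs used for training in each split.
#' @param init `"kmeans"` (default) warm-starts the network by a few epochs
#'   of cross-entropy toward one-hot k-means labels of the standardized
#'   training frames before the variational phase; `"random"` skips the
#'   warm start.  The warm start guarantees every output state begins
#'   populated: starting cold, the slowest contrast saturates first and the
#'   gradient that would split a prematurely merged state pair vanishes
#'   with it (a state-collapsed local optimum).
#' @param warmup_epochs warm-start epochs when `init = "kmeans"`.
#' @return a `net_config` list.
#' @export
net_config <- function(hidden = c(100, 100, 100, 100), lr = 1e-3,
                       batch_size = 1024, epochs = 50, patience = 10,
                       ridge = 0.01, train_fraction = 0.9,
                       init = c("kmeans", "random"), warmup_epochs = 3) {
  structure(list(hidden = as.integer(hidden), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 ridge = ridge, train_fraction = train_fraction,
                 init = match.arg(init),
                 warmup_epochs = as.integer(warmup_epochs)),
            class = "net_config")
}

standardizer_fit <- function(X) {
  m <- colMeans(X)
  s <- pmax(apply(X, 2, stats::sd), 1e-8)
  list(mean = m, sd = s)
}

standardize <- function(std, X) {
  if (is.null(dim(X))) X <- base::matrix(X, nrow = 1)
  sweep(sweep(X, 2, std$mean, `-`), 2, std$sd, `/`)
}

# VAMP-E score from output-probability batches at t and t + tau.
# Raw (non-mean-free) covariances keep the constant singular function in the
# basis, so a constant one-state model scores exactly 1.
vamp_e_from_probs <- function(PX, PY, ridge = 0) {
  n <- nrow(PX)
  C00 <- crossprod(PX) / n
  C0t <- crossprod(PX, PY) / n
  Ctt <- crossprod(PY) / n
  if (ridge > 0) {
    r <- ridge * mean(diag(C00) + diag(Ctt)) / 2
    C00 <- C00 + r * diag(ncol(PX))
    Ctt <- Ctt + r * diag(ncol(PY))
  }
  sum(diag(solve(C00, C0t) %*% solve(Ctt, t(C0t))))
}

#' VAMP-E score of a model on a set of frame pairs
#'
#' Computed from the instantaneous, time-lagged and cross covariance
#' matrices of the model's state-probability outputs over the pairs:
#' `tr[C00^-1 C0t Ctt^-1 C0t^T]`.  Includes the constant component, so a
#' one-state model scores 1; a model resolving the slowest process of a
#' two-state chain approaches `1 + lambda_2^2`.
#'
#' @param model a `soft_model` (or `model_ensemble`).
#' @param pairs a `frame_pair_set`.
#' @return the score (deterministic for fixed model and pairs).
#' @export
vamp_e_score <- function(model, pairs) {
  PX <- predict_probs(model, pairs$features[pairs$i0, , drop = FALSE])
  if (n_pairs(pairs) <= ncol(PX)) {
    stopf(paste0("only %d pairs for %d states: covariances are singular ",
                 "(supply more pairs, or regularize)"),
          n_pairs(pairs), ncol(PX))
  }
  PY <- predict_probs(model, pairs$features[pairs$i1, , drop = FALSE])
  tryCatch(vamp_e_from_probs(PX, PY),
           error = function(e) stopf(
             "singular output covariance: %s (consider a small ridge)",
             conditionMessage(e)))
}

# Gradient of the VAMP-E score w.r.t. the two probability batches.
vamp_e_grad <- function(PX, PY, ridge) {
  n <- nrow(PX)
  M <- ncol(PX)
  C00 <- crossprod(PX) / n
  C0t <- crossprod(PX, PY) / n
  Ctt <- crossprod(PY) / n
  r <- ridge * mean(diag(C00) + diag(Ctt)) / 2
  C00 <- C00 + r * diag(M)
  Ctt <- Ctt + r * diag(M)
  A <- solve(C00)
  B <- solve(Ctt)
  ACB <- A %*% C0t %*% B
  score <- sum(diag(ACB %*% t(C0t)))
  G00 <- -ACB %*% t(C0t) %*% A          # symmetric
  G0t <- 2 * ACB
  Gtt <- -B %*% t(C0t) %*% A %*% C0t %*% B
  list(score = score,
       dPX = (2 / n) * PX %*% G00 + (1 / n) * PY %*% t(G0t),
       dPY = (2 / n) * PY %*% Gtt + (1 / n) * PX %*% G0t)
}

#' Train a single soft model
#'
#' Maximizes the (regularized) VAMP-E score of the output covariances by
#' Adam over minibatches of time-lagged pairs, both lobes sharing one
#' parameter set.  The epoch with the best validation VAMP-E is kept
#' (early stopping with the configured patience).  Fully deterministic for a
#' fixed seed and configuration.
#'
#' @param train,validation `frame_pair_set`s from [split_pairs()].
#' @param M number of states (>= 2).
#' @param config a [net_config()].
#' @param seed training seed (initialization and batch shuffling).
#' @return an object of class `soft_model` with the recorded
#'   `validation_vamp_e`; the model carries a `low_score` warning flag when
#'   that score falls below the one-state baseline of 1.
#' @export
train_model <- function(train, validation, M, config = net_config(), seed = 1) {
  if (!is_count(M) || M < 2) stopf("M must be an integer >= 2")
  if (n_pairs(train) < 1) stopf("empty training pair set")
  F <- ncol(train$features)
  idx_frames <- unique(c(train$i0, train$i1))
  std <- standardizer_fit(train$features[idx_frames, , drop = FALSE])
  Xall <- standardize(std, train$features)
  VX <- Xall[validation$i0, , drop = FALSE]
  VY <- Xall[validation$i1, , drop = FALSE]
  net <- net_init(c(F, config$hidden, M), derive_seed(seed, 101L))
  opt <- adam_init(net)
  n <- n_pairs(train)
  bs <- min(config$batch_size, n)
  if (config$init == "kmeans" && config$warmup_epochs > 0) {
    # geometric warm start: a few cross-entropy epochs toward one-hot
    # k-means labels keep every output state populated before the
    # variational phase takes over
    sub <- if (length(idx_frames) > 20000) {
      with_seed(derive_seed(seed, 103L), sample(idx_frames, 20000))
    } else idx_frames
    km <- with_seed(derive_seed(seed, 104L),
                    stats::kmeans(Xall[sub, , drop = FALSE], centers = M,
                                  nstart = 3, iter.max = 50))
    Yk <- base::matrix(0, length(sub), M)
    Yk[cbind(seq_along(sub), km$cluster)] <- 1
    for (epoch in seq_len(config$warmup_epochs)) {
      ord <- with_seed(derive_seed(seed, c(105L, epoch)),
                       sample.int(length(sub)))
      for (s0 in seq(1L, length(sub), by = bs)) {
        b <- ord[s0:min(s0 + bs - 1L, length(sub))]
        fx <- net_forward(net, Xall[sub[b], , drop = FALSE], cache = TRUE)
        dZ <- (fx$P - Yk[b, , drop = FALSE]) / length(b)
        gr <- net_backward(net, fx, dZ = dZ)
        upd <- adam_step(net, gr, opt, config$lr)
        net <- upd$net
        opt <- upd$state
      }
    }
  }
  best <- list(score = -Inf, net = net)
  stall <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(seed, c(102L, epoch)), sample.int(n))
    starts <- seq(1L, n, by = bs)
    for (s0 in starts) {
      b <- ord[s0:min(s0 + bs - 1L, n)]
      if (length(b) <= M) next  # degenerate tail batch
      BX <- Xall[train$i0[b], , drop = FALSE]
      BY <- Xall[train$i1[b], , drop = FALSE]
      fx <- net_forward(net, BX, cache = TRUE)
      fy <- net_forward(net, BY, cache = TRUE)
      g <- vamp_e_grad(fx$P, fy$P, config$ridge)
      if (!is.finite(g$score)) {
        stopf("non-finite training score at epoch %d (lr %.3g, ridge %.3g)",
              epoch, config$lr, config$ridge)
      }
      gx <- net_backward(net, fx, -g$dPX)  # ascent on the score
      gy <- net_backward(net, fy, -g$dPY)
      grads <- list(gW = Map(`+`, gx$gW, gy$gW), gb = Map(`+`, gx$gb, gy$gb))
      upd <- adam_step(net, grads, opt, config$lr)
      net <- upd$net
      opt <- upd$state
    }
    val <- vamp_e_from_probs(net_forward(net, VX), net_forward(net, VY),
                             ridge = 1e-10)
    if (val > best$score + 1e-12) {
      best <- list(score = val, net = net)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  low <- best$score < 1
  if (low) {
    warnf("validation VAMP-E %.4f below the one-state baseline of 1", best$score)
  }
  structure(list(W = best$net$W, b = best$net$b, dims = best$net$dims, M = M,
                 lag_steps = train$lag_steps,
                 frame_interval = train$frame_interval, standardizer = std,
                 validation_vamp_e = best$score, init_seed = as.integer(seed),
                 config = config, low_score = low),
            class = "soft_model")
}

#' @export
print.soft_model <- function(x, ...) {
  cat(sprintf(paste0("soft_model: %d features -> [%s] -> %d states, ",
                     "lag %d steps, validation VAMP-E %.4f\n"),
              x$dims[1], paste(x$config$hidden, collapse = ","), x$M,
              x$lag_steps, x$validation_vamp_e))
  invisible(x)
}

# Internal dispatcher: state probabilities of frames under a model-like
# object (raw model, permutation-corrected model, whole ensemble, or a plain
# function frames -> probability matrix, e.g. an exact Bayes classifier).
predict_probs <- function(object, frames) {
  if (is.null(dim(frames))) frames <- base::matrix(frames, nrow = 1)
  if (is.function(object)) {
    P <- object(frames)
    if (is.null(dim(P))) P <- base::matrix(P, nrow = nrow(frames))
    return(P)
  }
  if (inherits(object, "soft_model")) {
    return(net_forward(list(W = object$W, b = object$b),
                       standardize(object$standardizer, frames)))
  }
  if (inherits(object, "aligned_soft_model")) {
    P <- predict_probs(object$model, frames)
    return(P[, order(object$perm), drop = FALSE])
  }
  if (inherits(object, "model_ensemble")) return(soft_assign(object, frames))
  stopf("cannot compute state probabilities for class '%s'", class(object)[1])
}

#' @export
predict.soft_model <- function(object, newdata, ...) {
  predict_probs(object, newdata)
}

# A model viewed in the ensemble's common state order: aligned column c is
# the model's output node k with perm[k] == c.
aligned_model <- function(ensemble, n) {
  structure(list(model = ensemble$models[[n]],
                 perm = ensemble$state_permutations[[n]]),
            class = "aligned_soft_model")
}

#' Train an aligned ensemble of soft models
#'
#' Builds N random 90/10 splits of the time-lagged pairs; per split trains
#' `inits_per_split` models from distinct derived seeds and keeps the one
#' with the highest validation VAMP-E; then computes per-model per-state
#' average feature matrices and aligns all models to a common state order by
#' constrained k-means.
#'
#' @param dataset a [trajectory_dataset()].
#' @param M number of states.
#' @param lag_steps lag in saved-frame steps.
#' @param N ensemble size (default 20).
#' @param inits_per_split initializations per split (default 3).
#' @param config a [net_config()].
#' @param seed master seed; all split/init/alignment seeds derive from it.
#' @param xi_frames optional frame matrix over which the state feature
#'   matrices are averaged (default: all frames of the dataset).
#' @param xi_weighting `"soft"` or `"hard"` averaging (see
#'   [state_feature_matrices()]).
#' @return an object of class `model_ensemble`.
#' @export
train_ensemble <- function(dataset, M, lag_steps, N = 20, inits_per_split = 3,
                           config = net_config(), seed = 1, xi_frames = NULL,
                           xi_weighting = "soft") {
  pairs <- make_frame_pairs(dataset, lag_steps)
  splits <- split_pairs(pairs, n_splits = N,
                        train_fraction = config$train_fraction,
                        seed = derive_seed(seed, 1L))
  models <- vector("list", N)
  candidate_scores <- base::matrix(NA_real_, N, inits_per_split)
  for (s in seq_len(N)) {
    cands <- vector("list", inits_per_split)
    for (k in seq_len(inits_per_split)) {
      cands[[k]] <- tryCatch(
        suppressWarnings(
          train_model(splits[[s]]$train, splits[[s]]$validation, M,
                      config = config, seed = derive_seed(seed, c(2L, s, k)))),
        error = function(e) e)
    }
    ok <- !vapply(cands, inherits, logical(1), "error")
    if (!any(ok)) {
      stopf("all %d trainings failed for split %d: %s", inits_per_split, s,
            conditionMessage(cands[[1]]))
    }
    candidate_scores[s, ok] <- vapply(cands[ok], `[[`, numeric(1),
                                      "validation_vamp_e")
    models[[s]] <- cands[ok][[which.max(candidate_scores[s, ok])]]
  }
  if (is.null(xi_frames)) xi_frames <- dataset_matrix(dataset)
  xi <- state_feature_matrices(models, xi_frames, weighting = xi_weighting)
  wa <- align_within_system(xi, init_model = "random",
                            seed = derive_seed(seed, 3L))
  structure(list(models = models, candidate_scores = candidate_scores,
                 state_permutations = wa$permutations,
                 state_feature_matrices = xi, within_alignment = wa,
                 M = as.integer(M), lag_steps = as.integer(lag_steps),
                 frame_interval = dataset$frame_interval,
                 system_label = dataset$system_label,
                 seed = as.integer(seed)),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  sc <- vapply(x$models, `[[`, numeric(1), "validation_vamp_e")
  cat(sprintf(paste0("model_ensemble '%s': %d models, %d states, lag %d ",
                     "steps\n  validation VAMP-E: median %.4f ",
                     "[%.4f, %.4f]\n"),
              x$system_label, length(x$models), x$M, x$lag_steps,
              stats::median(sc), min(sc), max(sc)))
  invisible(x)
}

#' Ensemble soft assignment of frames
#'
#' The soft assignment of a frame is the average of its permutation-corrected
#' state probabilities across the ensemble's models.
#'
#' @param ensemble an aligned `model_ensemble`.
#' @param frames `n x F` matrix (or a single feature vector).
#' @return `n x M` matrix of probabilities (rows sum to 1).
#' @export
soft_assign <- function(ensemble, frames) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (is.null(ensemble$state_permutations)) {
    stopf("ensemble is not aligned; run align_within_system first")
  }
  if (is.null(dim(frames))) frames <- base::matrix(frames, nrow = 1)
  acc <- 0
  for (n in seq_along(ensemble$models)) {
    acc <- acc + predict_probs(aligned_model(ensemble, n), frames)
  }
  acc / length(ensemble$models)
}

#' Ensemble hard assignment of frames
#'
#' The state with the highest soft-assignment probability; exact ties go to
#' the lowest state index.
#'
#' @inheritParams soft_assign
#' @return integer vector of state labels.
#' @export
hard_assign <- function(ensemble, frames) {
  max.col(soft_assign(ensemble, frames), ties.method = "first")
}
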