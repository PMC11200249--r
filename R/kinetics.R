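# Markov-state-model kinetics from soft state assignments.
#
# The propagator in the basis of the model's state-probability functions is
# the Koopman matrix K = C00^-1 C0t, built from the soft (probability
# weighted) covariances over time-lagged frame pairs.  K row-sums to 1 by
# construction and its eigenvalues are invariant to invertible mixing of
# the output states, so implied timescales are estimated consistently even
# when memberships are fuzzy (plain row-normalized soft counts are biased
# toward fast relaxation in that case).  In the constrained mode K is
# projected onto the reversible, non-negative transition matrices by the
# standard self-consistent reweighting iteration on the probability
# weighted flux matrix pi_i K_ij; detailed balance then holds by
# construction.

#' Estimate the transition (Koopman) matrix from a model and frame pairs
#'
#' @param model a `soft_model` (or any object `predict_probs` accepts,
#'   e.g. a `model_ensemble`).
#' @param pairs a `frame_pair_set` at the model's lag.
#' @param constraint_mode `"reversible-nonnegative"` (default) or
#'   `"unconstrained"` (plain row-normalized soft counts).
#' @param tol convergence tolerance of the reversible iteration.
#' @param max_iter iteration cap of the reversible iteration.
#' @return an object of class `koopman_estimate` with the row-stochastic
#'   matrix `T`, stationary vector `pi`, `lag_steps` and `lag_time` (ns).
#' @export
estimate_koopman <- function(model, pairs,
                             constraint_mode = c("reversible-nonnegative",
                                                 "unconstrained"),
                             tol = 1e-10, max_iter = 1e4) {
  constraint_mode <- match.arg(constraint_mode)
  X <- predict_probs(model, pairs$features[pairs$i0, , drop = FALSE])
  Y <- predict_probs(model, pairs$features[pairs$i1, , drop = FALSE])
  n <- nrow(X)
  C00 <- crossprod(X) / n
  C0t <- crossprod(X, Y) / n
  mass <- colSums(X) + colSums(Y)
  empty <- which(mass < 1e-8 * sum(mass))
  if (length(empty)) {
    stopf("state %d is never visited (column mass %.3g); cannot estimate",
          empty[1], mass[empty[1]])
  }
  K <- solve(C00, C0t)  # rows sum to 1 exactly; may have small negatives
  if (constraint_mode == "unconstrained") {
    T <- K
    pi <- stationary_distribution(pmax(T, 0) / rowSums(pmax(T, 0)))
  } else {
    pi_K <- stationary_distribution(pmax(K, 0) / rowSums(pmax(K, 0)))
    flux <- pmax(pi_K * K, 0)  # probability-weighted flux pi_i K_ij
    rev <- reversible_mle(n * flux, tol = tol, max_iter = max_iter)
    T <- rev$T
    pi <- rev$pi
    assert_stochastic(T)
  }
  structure(list(T = T, pi = pi, lag_steps = pairs$lag_steps,
                 lag_time = pairs$lag_steps * pairs$frame_interval,
                 constraint_mode = constraint_mode,
                 n_pairs = n_pairs(pairs)),
            class = "koopman_estimate")
}

#' @export
print.koopman_estimate <- function(x, ...) {
  cat(sprintf("koopman_estimate: %d states at lag %g ns (%s, %d pairs)\n",
              nrow(x$T), x$lag_time, x$constraint_mode, x$n_pairs))
  cat("pi:", paste(sprintf("%.4f", x$pi), collapse = " "), "\n")
  invisible(x)
}

# Maximum-likelihood reversible transition matrix from a count matrix.
# Fixed-point iteration: x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j),
# where c_i, x_i are row sums; T = x_ij / x_i, pi = x_i / sum(x).
reversible_mle <- function(C, tol = 1e-10, max_iter = 1e4) {
  Csym <- C + t(C)
  X <- Csym
  ci <- rowSums(C)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, `+`)
    Xn <- Csym / denom
    delta <- max(abs(Xn / sum(Xn) - X / sum(X)))
    X <- Xn
    if (delta < tol) break
  }
  xi <- rowSums(X)
  list(T = X / xi, pi = xi / sum(xi), iterations = it)
}

#' Stationary distribution of a transition matrix
#'
#' Dominant left eigenvector, normalized to sum 1.
#'
#' @param T row-stochastic irreducible matrix.
#' @param tol tolerance for the irreducibility / realness checks.
#' @return probability vector.
#' @export
equilibrium_distribution <- function(T, tol = 1e-8) {
  assert_stochastic(T)
  if (is_reducible(T)) stopf("transition matrix is reducible")
  e <- eigen(t(T))
  k <- which.max(Re(e$values))
  if (abs(Im(e$values[k])) > tol) {
    stopf("dominant eigenvalue is complex beyond tolerance")
  }
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  pmax(v, 0) / sum(pmax(v, 0))
}

# Reachability check on the support graph.
is_reducible <- function(T, tol = 1e-12) {
  M <- nrow(T)
  A <- (T > tol) | diag(M) > 0
  reach <- A
  for (k in seq_len(M)) reach <- (reach %*% A + reach) > 0
  !all(reach)
}

#' Mean first-passage times of the jump chain
#'
#' `mfpt[i, j]` is the expected physical time to first reach state j from
#' state i under the tau-jump chain, from the standard linear system
#' `(I - T[-j, -j]) m = 1` scaled by the lag time.  Diagonal is 0.
#'
#' @param T row-stochastic irreducible transition matrix at lag tau.
#' @param lag_time physical lag time (same units as the result).
#' @return `M x M` matrix of mean first-passage times.
#' @export
mean_first_passage_times <- function(T, lag_time = 1) {
  assert_stochastic(T)
  M <- nrow(T)
  out <- base::matrix(0, M, M)
  for (j in seq_len(M)) {
    Q <- T[-j, -j, drop = FALSE]
    m <- tryCatch(solve(diag(M - 1L) - Q, rep(1, M - 1L)),
                  error = function(e) stopf(
                    "first-passage system to state %d is singular (reducible chain?)", j))
    out[-j, j] <- m * lag_time
  }
  out
}

#' Implied timescales across lag times
#'
#' For each lag, estimates the transition matrix from the supplied model(s)
#' and reports `t_i = -tau / ln |lambda_i|` for the non-unit eigenvalues,
#' sorted by decreasing timescale.  Non-positive eigenvalues (possible in
#' unconstrained estimates) yield `NA` with a flag rather than an error.
#'
#' @param models_by_lag named list keyed by lag steps; each element a
#'   `soft_model` or a list of models (an ensemble's worth).
#' @param pairs_by_lag list of `frame_pair_set`s with matching names.
#' @param constraint_mode passed to [estimate_koopman()].
#' @return data frame with columns `lag_steps`, `lag_time`, `model`,
#'   `process` (2 = slowest non-stationary), `eigenvalue`, `timescale`,
#'   `flagged`.
#' @export
implied_timescales <- function(models_by_lag, pairs_by_lag,
                               constraint_mode = "reversible-nonnegative") {
  lags <- names(models_by_lag)
  if (length(lags) < 2) stopf("implied timescales need at least 2 lags")
  if (!setequal(lags, names(pairs_by_lag))) {
    stopf("models_by_lag and pairs_by_lag must share names (lags)")
  }
  rows <- list()
  for (lg in lags) {
    ms <- models_by_lag[[lg]]
    if (inherits(ms, "soft_model") || is.function(ms)) ms <- list(ms)
    for (n in seq_along(ms)) {
      est <- estimate_koopman(ms[[n]], pairs_by_lag[[lg]],
                              constraint_mode = constraint_mode)
      ev <- eigen(est$T, only.values = TRUE)$values
      ev <- Re(ev)[order(-abs(ev))]
      for (p in 2:length(ev)) {
        flag <- ev[p] <= 0
        rows[[length(rows) + 1L]] <- data.frame(
          lag_steps = as.integer(lg), lag_time = est$lag_time, model = n,
          process = p, eigenvalue = ev[p],
          timescale = if (flag) NA_real_ else -est$lag_time / log(abs(ev[p])),
          flagged = flag)
      }
    }
  }
  do.call(rbind, rows)
}

#' Chapman-Kolmogorov test
#'
#' Compares `T(tau)^k` (predicted) against the transition matrix estimated
#' directly at lag `k * tau` for k = 1..k_max.  For a Markovian system the
#' two agree within sampling error.
#'
#' @param model a `soft_model` or `model_ensemble`.
#' @param dataset the [trajectory_dataset()] to estimate from.
#' @param lag_steps base lag tau in steps.
#' @param k_max largest multiple tested.
#' @param constraint_mode passed to [estimate_koopman()].
#' @return an object of class `ck_test`: per-k predicted and estimated
#'   matrices, per-state occupation curves (diagonal entries) and the
#'   maximum entrywise discrepancy per k.
#' @export
chapman_kolmogorov <- function(model, dataset, lag_steps, k_max = 5,
                               constraint_mode = "reversible-nonnegative") {
  base_pairs <- make_frame_pairs(dataset, lag_steps)
  T1 <- estimate_koopman(model, base_pairs, constraint_mode)$T
  M <- nrow(T1)
  predicted <- estimated <- vector("list", k_max)
  discrepancy <- numeric(k_max)
  Tk <- diag(M)
  ks <- integer(0)
  for (k in seq_len(k_max)) {
    Tk <- Tk %*% T1
    est <- tryCatch(
      estimate_koopman(model, make_frame_pairs(dataset, k * lag_steps),
                       constraint_mode)$T,
      error = function(e) NULL)
    if (is.null(est)) {
      warnf("no pairs at lag %d steps; truncating CK test at k = %d",
            k * lag_steps, k - 1L)
      break
    }
    predicted[[k]] <- Tk
    estimated[[k]] <- est
    discrepancy[k] <- max(abs(Tk - est))
    ks <- c(ks, k)
  }
  occ <- do.call(rbind, lapply(ks, function(k) data.frame(
    k = k, state = seq_len(M),
    predicted = diag(predicted[[k]]), estimated = diag(estimated[[k]]))))
  structure(list(k = ks, predicted = predicted[ks], estimated = estimated[ks],
                 discrepancy = discrepancy[ks], occupation = occ,
                 lag_steps = lag_steps),
            class = "ck_test")
}

#' @export
print.ck_test <- function(x, ...) {
  cat(sprintf("ck_test at base lag %d steps: max discrepancy by k:\n",
              x$lag_steps))
  print(round(stats::setNames(x$discrepancy, paste0("k=", x$k)), 4))
  invisible(x)
}

#' Ensemble kinetics summary with percentile bands
#'
#' Per-model equilibrium distributions, mean first-passage times and slowest
#' implied timescales, summarized by the median and the 95th-percentile band
#' centered on the median (quantiles 0.025 and 0.975, linear interpolation).
#'
#' @param ensemble a `model_ensemble`.
#' @param pairs a `frame_pair_set` at the ensemble lag.
#' @param constraint_mode passed to [estimate_koopman()].
#' @return an object of class `kinetics_summary`.
#' @export
kinetics_summary <- function(ensemble, pairs,
                             constraint_mode = "reversible-nonnegative") {
  stopifnot(inherits(ensemble, "model_ensemble"))
  ests <- lapply(seq_along(ensemble$models), function(n) {
    est <- estimate_koopman(aligned_model(ensemble, n), pairs, constraint_mode)
    ev <- sort(abs(Re(eigen(est$T, only.values = TRUE)$values)),
               decreasing = TRUE)
    list(pi = est$pi,
         mfpt = mean_first_passage_times(est$T, est$lag_time),
         t2 = if (ev[2] > 0) -est$lag_time / log(ev[2]) else NA_real_,
         T = est$T, lag_time = est$lag_time)
  })
  band <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), na.rm = TRUE,
                                      type = 7)
  M <- length(ests[[1]]$pi)
  pi_mat <- do.call(rbind, lapply(ests, `[[`, "pi"))
  mfpt_arr <- simplify2array(lapply(ests, `[[`, "mfpt"))
  structure(list(
    pi = apply(pi_mat, 2, band),
    mfpt = apply(mfpt_arr, c(1, 2), stats::median),
    mfpt_band = apply(mfpt_arr, c(1, 2), band),
    t2 = band(vapply(ests, `[[`, numeric(1), "t2")),
    T_median = apply(simplify2array(lapply(ests, `[[`, "T")), c(1, 2),
                     stats::median),
    lag_time = ests[[1]]$lag_time, per_model = ests),
    class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf("kinetics_summary at lag %g ns (%d models)\n", x$lag_time,
              length(x$per_model)))
  cat("equilibrium (median [2.5%, 97.5%]):\n")
  for (m in seq_len(ncol(x$pi))) {
    cat(sprintf("  state %d: %.3f [%.3f, %.3f]\n", m, x$pi["50%", m],
                x$pi["2.5%", m], x$pi["97.5%", m]))
  }
  cat(sprintf("slowest implied timescale t2: %.3g [%.3g, %.3g] ns\n",
              x$t2[["50%"]], x$t2[["2.5%"]], x$t2[["97.5%"]]))
  cat("median MFPT matrix (ns):\n")
  print(round(x$mfpt, 2))
  invisible(x)
}
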