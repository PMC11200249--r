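# tICA projection and kernel-density free-energy surfaces.

#' Fit a two-component tICA projection
#'
#' Solves the generalized eigenproblem of the symmetrized time-lagged
#' covariance against the instantaneous covariance (reversible estimator):
#' both matrices are estimated mean-free over the union of the t and t+tau
#' frames, the instantaneous covariance is whitened (small eigenvalues
#' floored with a warning when rank-deficient), and the top two components
#' by eigenvalue are retained.
#'
#' @param dataset a [trajectory_dataset()].
#' @param lag_steps tICA lag in saved-frame steps.
#' @param n_components components kept (default 2).
#' @param eps relative eigenvalue floor for the whitening step.
#' @return an object of class `tica_projection`: per-frame component
#'   coordinates (`components`, frames stacked trajectory-major),
#'   `eigenvalues`, the centering `mean` and the `projection` matrix.
#' @export
fit_tica <- function(dataset, lag_steps, n_components = 2, eps = 1e-10) {
  pairs <- make_frame_pairs(dataset, lag_steps)
  X <- pairs$features[pairs$i0, , drop = FALSE]
  Y <- pairs$features[pairs$i1, , drop = FALSE]
  mu <- colMeans(rbind(X, Y))
  Xc <- sweep(X, 2, mu)
  Yc <- sweep(Y, 2, mu)
  n <- nrow(Xc)
  C0 <- (crossprod(Xc) + crossprod(Yc)) / (2 * n)
  Ct <- (crossprod(Xc, Yc) + crossprod(Yc, Xc)) / (2 * n)
  e0 <- eigen(C0, symmetric = TRUE)
  floor_val <- eps * max(e0$values)
  if (any(e0$values < floor_val)) {
    warnf("instantaneous covariance is rank-deficient; %d eigenvalues floored",
          sum(e0$values < floor_val))
  }
  d <- pmax(e0$values, floor_val)
  Wh <- e0$vectors %*% diag(1 / sqrt(d), length(d))
  es <- eigen(crossprod(Wh, Ct %*% Wh), symmetric = TRUE)
  k <- seq_len(min(n_components, length(es$values)))
  P <- Wh %*% es$vectors[, k, drop = FALSE]
  comps <- sweep(dataset_matrix(dataset), 2, mu) %*% P
  colnames(comps) <- paste0("tIC", k)
  structure(list(components = comps, eigenvalues = es$values[k],
                 lag_steps = as.integer(lag_steps), mean = mu, projection = P),
            class = "tica_projection")
}

#' @export
print.tica_projection <- function(x, ...) {
  cat(sprintf("tica_projection: %d frames on %d components at lag %d steps\n",
              nrow(x$components), ncol(x$components), x$lag_steps))
  cat("eigenvalues:", paste(sprintf("%.4f", x$eigenvalues), collapse = " "), "\n")
  invisible(x)
}

#' Project new frames onto a fitted tICA basis
#'
#' @param object a `tica_projection`.
#' @param newdata `n x F` feature matrix.
#' @param ... unused.
#' @return `n x k` component coordinates.
#' @export
predict.tica_projection <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- base::matrix(newdata, nrow = 1)
  sweep(newdata, 2, object$mean) %*% object$projection
}

#' Free-energy surface on the first two tICA components
#'
#' Gaussian kernel density estimation on a seed-controlled random subsample
#' of the projected frames (default 10%), on a regular grid padded 5% beyond
#' the data extent; the surface is `-ln p` in kT units, shifted so its
#' minimum is 0.  Bandwidths follow Scott's rule (`sd * n^(-1/6)` per
#' dimension) times `bw_scale`.
#'
#' @param projection a `tica_projection` (or an `n x 2` coordinate matrix).
#' @param subsample_fraction fraction of frames used (default 0.1).
#' @param seed subsampling seed.
#' @param grid_size grid resolution per axis (default 100).
#' @param bw_scale bandwidth multiplier.
#' @param pad extent padding fraction.
#' @return an object of class `free_energy_surface` with grid axes `x`, `y`
#'   and the energy matrix `F` (kT).
#' @export
estimate_fes <- function(projection, subsample_fraction = 0.1, seed = 1,
                         grid_size = 100, bw_scale = 1, pad = 0.05) {
  if (!(subsample_fraction > 0 && subsample_fraction <= 1)) {
    stopf("subsample_fraction must lie in (0, 1]")
  }
  Z <- if (inherits(projection, "tica_projection")) {
    projection$components[, 1:2, drop = FALSE]
  } else projection
  if (ncol(Z) < 2) stopf("need two projection components")
  n <- nrow(Z)
  m <- round(subsample_fraction * n)
  if (m < 100) {
    stopf("subsample of %d frames is too small (need >= 100)", m)
  }
  sel <- if (m == n) seq_len(n) else with_seed(seed, sample.int(n, m))
  S <- Z[sel, , drop = FALSE]
  bw <- apply(S, 2, stats::sd) * m^(-1 / 6) * bw_scale
  rng <- apply(S, 2, range)
  span <- rng[2, ] - rng[1, ]
  lims <- c(rng[1, 1] - pad * span[1], rng[2, 1] + pad * span[1],
            rng[1, 2] - pad * span[2], rng[2, 2] + pad * span[2])
  # MASS::kde2d's h is 4x the kernel sd
  kd <- MASS::kde2d(S[, 1], S[, 2], h = 4 * bw, n = grid_size, lims = lims)
  Fmat <- -log(kd$z)
  Fmat <- Fmat - min(Fmat)
  structure(list(x = kd$x, y = kd$y, F = Fmat, bandwidth = bw,
                 subsample_fraction = subsample_fraction,
                 n_points = m, grid_size = as.integer(grid_size)),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf(paste0("free_energy_surface: %d x %d grid from %d points ",
                     "(%.0f%% subsample), F range [0, %.3g] kT\n"),
              x$grid_size, x$grid_size, x$n_points,
              100 * x$subsample_fraction, max(x$F[is.finite(x$F)])))
  invisible(x)
}

#' Local minima (basins) of a free-energy surface
#'
#' Grid cells whose energy is below all 8 neighbours and below `max_energy`.
#' Convenience for tests and state-overlay plots.
#'
#' @param fes a `free_energy_surface`.
#' @param max_energy only minima below this energy (kT) are reported.
#' @return data frame with columns `x`, `y`, `F`.
#' @export
fes_minima <- function(fes, max_energy = 3) {
  Fm <- fes$F
  n <- nrow(Fm)
  hits <- NULL
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      nb <- Fm[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (Fm[i, j] <= max_energy && Fm[i, j] < min(nb[-5])) {
        hits <- rbind(hits, data.frame(x = fes$x[i], y = fes$y[j],
                                       F = Fm[i, j]))
      }
    }
  }
  hits %||% data.frame(x = numeric(0), y = numeric(0), F = numeric(0))
}
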