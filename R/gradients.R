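# Gradient-based characterization of learned states.
#
# For a state m, g_m is the gradient of the ensemble's output probability of
# m with respect to the input inter-residue distances, averaged over the
# (permutation-corrected) models and over a random sample of frames.  The
# sign convention is fixed: a positive entry means the state probability
# increases when that residue-pair distance increases.  Gradients are
# reported per Angstrom of raw distance (chain-ruled through the input
# standardizer).

new_gradient_map <- function(g, n_residues, state, n_frames_averaged,
                             condition_state = NA_integer_) {
  mat <- devectorize(g, n_residues)
  structure(list(
    g = g, matrix_form = mat, n_residues = as.integer(n_residues),
    state = as.integer(state), n_frames_averaged = as.integer(n_frames_averaged),
    condition_state = condition_state,
    per_residue_signed = residue_profile(mat, abs_values = FALSE),
    per_residue_abs = residue_profile(mat, abs_values = TRUE),
    sign_convention = "positive => probability increases when distance increases"),
    class = "gradient_map")
}

#' @export
print.gradient_map <- function(x, ...) {
  cat(sprintf(paste0("gradient_map for state %d: %d features (%d x %d ",
                     "matrix), averaged over %d frames%s\n"),
              x$state, length(x$g), x$n_residues, x$n_residues,
              x$n_frames_averaged,
              if (is.na(x$condition_state)) "" else
                sprintf(" conditioned on state %d", x$condition_state)))
  cat(sprintf("|g| range: [%.3g, %.3g]; %s\n", min(abs(x$g)), max(abs(x$g)),
              x$sign_convention))
  invisible(x)
}

residue_profile <- function(mat, abs_values) {
  M <- mat
  M[is.na(M)] <- 0
  if (abs_values) M <- abs(M)
  rowSums(M)
}

#' Gradient of one state's probability for individual frames
#'
#' Exact gradient (backpropagation) of the model's output probability of
#' `state` with respect to the raw, unstandardized input features.
#'
#' @param model a `soft_model`.
#' @param frame a feature vector, or an `n x F` matrix of frames.
#' @param state state index in 1..M.
#' @return gradient vector of length F (or `n x F` matrix for several
#'   frames).
#' @export
frame_gradient <- function(model, frame, state) {
  stopifnot(inherits(model, "soft_model"))
  if (!is_count(state) || state > model$M) {
    stopf("state must lie in 1..%d", model$M)
  }
  X <- if (is.null(dim(frame))) base::matrix(frame, nrow = 1) else frame
  G <- net_input_gradient(list(W = model$W, b = model$b),
                          standardize(model$standardizer, X), state)
  G <- sweep(G, 2, model$standardizer$sd, `/`)  # d std / d raw = 1 / sd
  if (any(!is.finite(G))) {
    stopf("non-finite gradient at frame %d", which(!is.finite(rowSums(G)))[1])
  }
  if (is.null(dim(frame))) drop(G) else G
}

# Model-level gradient in the ensemble's common state order.
aligned_frame_gradient <- function(ensemble, n, frames, state) {
  node <- which(ensemble$state_permutations[[n]] == state)
  frame_gradient(ensemble$models[[n]], frames, node)
}

#' Ensemble-averaged gradient map of a state
#'
#' Averages the per-frame gradients over the ensemble's
#' permutation-corrected models and over `n_frames` frames sampled uniformly
#' without replacement (seed-controlled), then arranges the result into the
#' distance-matrix shape and aggregates it per residue.
#'
#' @param ensemble an aligned `model_ensemble`.
#' @param dataset a [trajectory_dataset()] (or an `n x F` frame matrix).
#' @param state state index in the common order.
#' @param n_frames frames to average over (default 10000; the whole dataset
#'   with a warning when smaller).
#' @param seed sampling seed.
#' @return a `gradient_map`.
#' @export
ensemble_gradient <- function(ensemble, dataset, state, n_frames = 10000,
                              seed = 1) {
  frames <- if (inherits(dataset, "trajectory_dataset")) {
    dataset_matrix(dataset)
  } else dataset
  gradient_over_frames(ensemble, frames, state, n_frames, seed,
                       condition_state = NA_integer_)
}

#' Gradient map evaluated on state-specific frames
#'
#' As [ensemble_gradient()], but samples only frames whose ensemble hard
#' assignment equals `condition_state`.
#'
#' @inheritParams ensemble_gradient
#' @param condition_state hard-assignment label the sampled frames must
#'   carry.
#' @export
state_conditioned_gradient <- function(ensemble, dataset, state,
                                       condition_state, n_frames = 10000,
                                       seed = 1) {
  if (!is_count(condition_state) || condition_state > ensemble$M) {
    stopf("condition_state must lie in 1..%d", ensemble$M)
  }
  frames <- if (inherits(dataset, "trajectory_dataset")) {
    dataset_matrix(dataset)
  } else dataset
  keep <- hard_assign(ensemble, frames) == condition_state
  if (!any(keep)) stopf("no frames are hard-assigned to state %d",
                        condition_state)
  if (sum(keep) < 100) {
    warnf("only %d frames hard-assigned to state %d; proceeding with those",
          sum(keep), condition_state)
  }
  gradient_over_frames(ensemble, frames[keep, , drop = FALSE], state,
                       n_frames, seed, condition_state = as.integer(condition_state))
}

gradient_over_frames <- function(ensemble, frames, state, n_frames, seed,
                                 condition_state) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (!is_count(state) || state > ensemble$M) {
    stopf("state must lie in 1..%d", ensemble$M)
  }
  n_avail <- nrow(frames)
  if (n_avail < n_frames) {
    warnf("dataset has %d frames < n_frames = %d; using all frames",
          n_avail, n_frames)
    sel <- seq_len(n_avail)
  } else {
    sel <- with_seed(seed, sample.int(n_avail, n_frames))
  }
  S <- frames[sel, , drop = FALSE]
  acc <- 0
  for (n in seq_along(ensemble$models)) {
    acc <- acc + colMeans(aligned_frame_gradient(ensemble, n, S, state))
  }
  g <- acc / length(ensemble$models)
  R <- residues_from_features(length(g))
  new_gradient_map(g, R, state, length(sel), condition_state)
}

# Invert F = (R-2)(R-3)/2.
residues_from_features <- function(F) {
  R <- round((5 + sqrt(1 + 8 * F)) / 2)
  if (feature_count(R) != F) {
    stopf("%d features do not correspond to an integer residue count", F)
  }
  as.integer(R)
}

#' Aggregate a gradient map per residue
#'
#' For each residue r, sums the (signed or absolute) gradient entries of all
#' kept pairs involving r.
#'
#' @param g a `gradient_map`.
#' @param mode `"abs-sum"` (importance profile, default) or `"signed-sum"`.
#' @return numeric vector of length R.
#' @export
aggregate_by_residue <- function(g, mode = c("abs-sum", "signed-sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "gradient_map"))
  if (mode == "abs-sum") g$per_residue_abs else g$per_residue_signed
}
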