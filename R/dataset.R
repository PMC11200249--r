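# Trajectory datasets and time-lagged frame pairs.

#' Bundle featurized trajectories into a dataset
#'
#' @param trajectories list of `L x F` matrices, one per trajectory; all must
#'   share the feature dimension.
#' @param frame_interval physical time between saved frames (ns).
#' @param pair_index optional residue-pair table from [pair_index()].
#' @param mode featurization mode label.
#' @param system_label free-text provenance label.
#' @return an object of class `trajectory_dataset`.
#' @export
trajectory_dataset <- function(trajectories, frame_interval = 0.1,
                               pair_index = NULL, mode = NULL,
                               system_label = "") {
  if (!is.list(trajectories) || length(trajectories) == 0) {
    stopf("trajectories must be a non-empty list")
  }
  trajectories <- lapply(trajectories, function(t) {
    if (is.null(dim(t))) t <- base::matrix(t, nrow = 1)
    storage.mode(t) <- "double"
    t
  })
  F <- ncol(trajectories[[1]])
  lens <- vapply(trajectories, nrow, integer(1))
  if (any(lens == 0)) stopf("every trajectory must contain at least one frame")
  if (any(vapply(trajectories, ncol, integer(1)) != F)) {
    stopf("all trajectories must share one feature dimension")
  }
  if (!is.null(pair_index) && nrow(pair_index) != F) {
    stopf("pair_index has %d rows but features have dimension %d",
          nrow(pair_index), F)
  }
  structure(list(trajectories = trajectories, frame_interval = frame_interval,
                 pair_index = pair_index, mode = mode,
                 system_label = system_label),
            class = "trajectory_dataset")
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  lens <- vapply(x$trajectories, nrow, integer(1))
  cat(sprintf(paste0("trajectory_dataset '%s': %d trajectories, %d frames, ",
                     "%d features, frame interval %g ns\n"),
              x$system_label, length(lens), sum(lens),
              ncol(x$trajectories[[1]]), x$frame_interval))
  invisible(x)
}

n_frames <- function(dataset) sum(vapply(dataset$trajectories, nrow, integer(1)))

# All frames of the dataset stacked into one matrix (trajectory-major order).
dataset_matrix <- function(dataset) do.call(rbind, dataset$trajectories)

#' Build time-lagged frame pairs
#'
#' A trajectory of length L contributes the pairs (t, t + lag) for
#' t = 1..L - lag; pairs never cross trajectory boundaries.
#'
#' @param dataset a [trajectory_dataset()].
#' @param lag_steps lag in saved-frame steps (>= 1).
#' @return a `frame_pair_set`: the stacked frame matrix plus index vectors
#'   `i0` (frames at t) and `i1` (frames at t + lag).
#' @export
make_frame_pairs <- function(dataset, lag_steps) {
  if (!is_count(lag_steps)) stopf("lag_steps must be a positive integer")
  lag_steps <- as.integer(lag_steps)
  lens <- vapply(dataset$trajectories, nrow, integer(1))
  offs <- cumsum(c(0L, lens[-length(lens)]))
  i0 <- unlist(lapply(seq_along(lens), function(k) {
    if (lens[k] > lag_steps) offs[k] + seq_len(lens[k] - lag_steps) else integer(0)
  }), use.names = FALSE)
  if (length(i0) == 0) {
    stopf("no frame pairs: all trajectories are shorter than lag %d", lag_steps)
  }
  structure(list(features = dataset_matrix(dataset), i0 = i0,
                 i1 = i0 + lag_steps, lag_steps = lag_steps,
                 frame_interval = dataset$frame_interval,
                 split_id = NA_integer_, role = "all"),
            class = "frame_pair_set")
}

#' @export
print.frame_pair_set <- function(x, ...) {
  cat(sprintf("frame_pair_set: %d pairs at lag %d steps (%s%s)\n",
              length(x$i0), x$lag_steps, x$role,
              if (is.na(x$split_id)) "" else sprintf(", split %d", x$split_id)))
  invisible(x)
}

n_pairs <- function(pairs) length(pairs$i0)

pairs_subset <- function(pairs, idx, split_id, role) {
  out <- pairs
  out$i0 <- pairs$i0[idx]
  out$i1 <- pairs$i1[idx]
  out$split_id <- as.integer(split_id)
  out$role <- role
  out
}

#' Random train/validation splits of a pair set
#'
#' Each split is an independent random partition of the pairs (splits are
#' resamples, not cross-validation folds).
#'
#' @param pairs a `frame_pair_set` from [make_frame_pairs()].
#' @param n_splits number of splits.
#' @param train_fraction fraction assigned to training (default 0.9).
#' @param seed master seed; per-split seeds are derived from it.
#' @return list of `n_splits` elements, each `list(train=, validation=)`.
#' @export
split_pairs <- function(pairs, n_splits = 20, train_fraction = 0.9, seed = 1) {
  if (!is_count(n_splits)) stopf("n_splits must be a positive integer")
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stopf("train_fraction must lie strictly between 0 and 1")
  }
  n <- n_pairs(pairs)
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n - n_train < 1) {
    stopf("%d pairs cannot be split %g/%g with non-empty parts",
          n, train_fraction, 1 - train_fraction)
  }
  lapply(seq_len(n_splits), function(s) {
    idx <- with_seed(derive_seed(seed, c(1L, s)), sample.int(n))
    list(train = pairs_subset(pairs, idx[seq_len(n_train)], s, "train"),
         validation = pairs_subset(pairs, idx[(n_train + 1):n], s, "validation"))
  })
}
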