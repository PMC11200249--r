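# Inter-residue distance featurization.
#
# A conformation of an R-residue chain is represented by the upper triangle
# of its R x R inter-residue distance matrix with the diagonal and the first
# two off-diagonal bands removed (sequence neighbours i,i+1 and i,i+2 carry
# no conformational signal).  That leaves F(R) = (R-2)(R-3)/2 distances; for
# a 42-residue peptide, 780.  Distances are in Angstrom.

#' Number of inter-residue distance features for an R-residue chain
#'
#' @param n_residues residue count.
#' @return `(R-2)(R-3)/2` for `R >= 4`, else 0.
#' @export
#' @examples
#' feature_count(42)  # 780
feature_count <- function(n_residues) {
  R <- as.integer(n_residues)
  ifelse(R >= 4L, (R - 2L) * (R - 3L) / 2L, 0L)
}

#' Residue-pair index underlying the feature vector
#'
#' Row-major ordering over the upper triangle: all pairs (i, j) with
#' `j - i >= 3`, i increasing, then j.  Residue indices are 1-based.
#'
#' @param n_residues residue count (>= 4).
#' @return two-column integer matrix with columns `i`, `j`.
#' @export
pair_index <- function(n_residues) {
  R <- as.integer(n_residues)
  if (R < 4L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  i <- rep.int(seq_len(R - 3L), times = (R - 3L):1L)
  j <- unlist(lapply(seq_len(R - 3L), function(k) (k + 3L):R), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Define a residue chain for featurization
#'
#' @param atom_groups list of integer vectors, one per residue, giving the
#'   (heavy-)atom indices of each residue within the coordinate array.
#' @param mode `"min-heavy-atom"` (distance between two residues is the
#'   minimum over their heavy-atom pairs) or `"c-alpha"` (distance between
#'   the designated C-alpha atoms).
#' @param ca_atoms for `"c-alpha"` mode, an integer vector with one atom
#'   index per residue; defaults to each group's single atom when all groups
#'   are singletons.
#' @return an object of class `residue_chain`.
#' @export
residue_chain <- function(atom_groups,
                          mode = c("min-heavy-atom", "c-alpha"),
                          ca_atoms = NULL) {
  mode <- match.arg(mode)
  if (!is.list(atom_groups) || length(atom_groups) == 0) {
    stopf("atom_groups must be a non-empty list of integer vectors")
  }
  n <- length(atom_groups)
  for (r in seq_len(n)) {
    g <- atom_groups[[r]]
    if (length(g) < 1 || any(!is.finite(g)) || any(g != round(g)) || any(g < 1)) {
      stopf("residue %d has no valid atom indices", r)
    }
  }
  if (mode == "c-alpha") {
    if (is.null(ca_atoms)) {
      if (all(lengths(atom_groups) == 1L)) {
        ca_atoms <- vapply(atom_groups, `[`, integer(1), 1L)
      } else {
        stopf("c-alpha mode needs ca_atoms (one atom index per residue)")
      }
    }
    if (length(ca_atoms) != n) {
      stopf("ca_atoms must have one entry per residue (%d != %d)",
            length(ca_atoms), n)
    }
    ca_atoms <- as.integer(ca_atoms)
  }
  structure(list(n_residues = n, atom_groups = lapply(atom_groups, as.integer),
                 mode = mode, ca_atoms = ca_atoms),
            class = "residue_chain")
}

#' @export
print.residue_chain <- function(x, ...) {
  cat(sprintf("residue_chain: %d residues, mode = %s, %d features\n",
              x$n_residues, x$mode, feature_count(x$n_residues)))
  invisible(x)
}

#' Compute inter-residue distance features from coordinates
#'
#' For each residue pair (i, j) with `j - i >= 3`, the distance is either the
#' minimum over heavy-atom pairs or the C-alpha distance, depending on the
#' chain's mode.  Units follow the coordinate units (Angstrom by convention).
#'
#' @param coordinates one frame as an `n_atoms x 3` matrix, or several frames
#'   as a list of such matrices or an `n_frames x n_atoms x 3` array.
#' @param chain a [residue_chain()].
#' @return a feature vector (single frame) or an `n_frames x F` matrix, with
#'   attributes `pair_index` and `mode`.
#' @export
compute_distance_features <- function(coordinates, chain) {
  if (!inherits(chain, "residue_chain")) stopf("chain must be a residue_chain")
  R <- chain$n_residues
  if (R < 4L) {
    stopf("chain has %d residues; at least 4 are needed for any feature", R)
  }
  frames <- normalize_frames(coordinates)
  n_atoms_needed <- max(unlist(chain$atom_groups),
                        if (chain$mode == "c-alpha") chain$ca_atoms else 0L)
  pi_tab <- pair_index(R)
  out <- matrix(NA_real_, nrow = length(frames), ncol = nrow(pi_tab))
  for (f in seq_along(frames)) {
    X <- frames[[f]]
    if (!is.matrix(X) || ncol(X) != 3) stopf("each frame must be an n_atoms x 3 matrix")
    if (nrow(X) < n_atoms_needed) {
      bad <- which(vapply(chain$atom_groups, function(g) max(g) > nrow(X), logical(1)))
      stopf("frame %d: coordinates missing atoms for residue %d", f,
            if (length(bad)) bad[1] else R)
    }
    out[f, ] <- frame_distances(X, chain, pi_tab)
  }
  structure(if (length(frames) == 1L) drop(out) else out,
            pair_index = pi_tab, mode = chain$mode)
}

normalize_frames <- function(coordinates) {
  if (is.list(coordinates)) return(coordinates)
  if (is.matrix(coordinates)) return(list(coordinates))
  if (is.array(coordinates) && length(dim(coordinates)) == 3) {
    return(lapply(seq_len(dim(coordinates)[1]),
                  function(f) coordinates[f, , , drop = TRUE]))
  }
  stopf("coordinates must be a matrix, a list of matrices, or a 3-d array")
}

frame_distances <- function(X, chain, pi_tab) {
  if (chain$mode == "c-alpha") {
    P <- X[chain$ca_atoms, , drop = FALSE]
    d2 <- P[pi_tab[, 1], , drop = FALSE] - P[pi_tab[, 2], , drop = FALSE]
    return(sqrt(rowSums(d2 * d2)))
  }
  groups <- chain$atom_groups
  vapply(seq_len(nrow(pi_tab)), function(k) {
    a <- X[groups[[pi_tab[k, 1]]], , drop = FALSE]
    b <- X[groups[[pi_tab[k, 2]]], , drop = FALSE]
    # minimum over the cross pairs of heavy atoms
    d2 <- outer(rowSums(a * a), rowSums(b * b), `+`) - 2 * tcrossprod(a, b)
    sqrt(max(0, min(d2)))
  }, numeric(1))
}

#' Extract the feature vector from a full distance matrix
#'
#' Inverse of [devectorize()]: pulls the entries (i, j) with `j - i >= 3`
#' from a symmetric distance matrix, in row-major order.
#'
#' @param matrix symmetric non-negative `R x R` matrix.
#' @param tol symmetry tolerance.
#' @return numeric feature vector of length `feature_count(R)`.
#' @export
vectorize <- function(matrix, tol = 1e-8) {
  M <- matrix
  if (!is.matrix(M) || nrow(M) != ncol(M)) stopf("input must be a square matrix")
  if (max(abs(M - t(M)), na.rm = TRUE) > tol) {
    stopf("matrix is asymmetric beyond tolerance %g", tol)
  }
  idx <- pair_index(nrow(M))
  M[idx]
}

#' Arrange a feature vector back into its distance-matrix shape
#'
#' @param v feature vector of length `(R-2)(R-3)/2`.
#' @param n_residues residue count R.
#' @param excluded value placed on the diagonal and the first two
#'   off-diagonal bands (default `NA`), marking entries that carry no
#'   feature.
#' @return symmetric `R x R` matrix.
#' @export
devectorize <- function(v, n_residues, excluded = NA_real_) {
  R <- as.integer(n_residues)
  expect <- feature_count(R)
  if (length(v) != expect) {
    stopf("feature vector has length %d; expected %d for %d residues",
          length(v), expect, R)
  }
  M <- base::matrix(excluded, R, R)
  idx <- pair_index(R)
  M[idx] <- v
  M[idx[, c(2, 1), drop = FALSE]] <- v
  M
}
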