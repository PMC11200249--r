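# Plain-text persistence: features as CSV with a JSON metadata sidecar,
# models and ensembles as JSON.

#' Write a featurized dataset to a directory
#'
#' One CSV per trajectory (`traj_0001.csv`, frames x features, no header
#' index) plus `features.json` holding the frame interval, featurization
#' mode, residue-pair table and system label.
#'
#' @param dataset a [trajectory_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_features <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(dataset$trajectories)) {
    utils::write.table(dataset$trajectories[[k]],
                       file.path(dir, sprintf("traj_%04d.csv", k)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(n_trajectories = length(dataset$trajectories),
               frame_interval = dataset$frame_interval,
               mode = dataset$mode, system_label = dataset$system_label,
               units = "angstrom",
               pair_index = dataset$pair_index)
  jsonlite::write_json(meta, file.path(dir, "features.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a featurized dataset written by [write_features()]
#'
#' @param dir directory containing `traj_*.csv` and `features.json`.
#' @param units units of the stored features; `"nm"` converts to Angstrom
#'   on ingest.
#' @return a [trajectory_dataset()].
#' @export
read_features <- function(dir, units = c("angstrom", "nm")) {
  units <- match.arg(units)
  meta_path <- file.path(dir, "features.json")
  if (!file.exists(meta_path)) stopf("no features.json in %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^traj_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0) stopf("no trajectory CSVs in %s", dir)
  scale <- if (units == "nm") 10 else 1
  trajs <- lapply(files, function(f) {
    m <- as.matrix(utils::read.table(f, sep = ",", header = FALSE)) * scale
    dimnames(m) <- NULL
    m
  })
  pi_tab <- meta$pair_index
  if (!is.null(pi_tab)) pi_tab <- as.matrix(pi_tab)
  trajectory_dataset(trajs, frame_interval = meta$frame_interval %||% 0.1,
                     pair_index = pi_tab, mode = meta$mode,
                     system_label = meta$system_label %||% "")
}

#' Save / load a trained soft model as JSON
#'
#' The checkpoint holds the weights, standardizer, dimensions, lag, seeds,
#' configuration and validation score.
#'
#' @param model a `soft_model`.
#' @param path output file.
#' @return `path` invisibly ([save_model()]); the model ([load_model()]).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "soft_model"))
  x <- unclass(model)
  x$config <- unclass(x$config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild_model(x)
}

rebuild_model <- function(x) {
  x$W <- lapply(x$W, as.matrix)
  x$b <- lapply(x$b, as.numeric)
  x$dims <- as.integer(x$dims)
  x$config <- structure(x$config, class = "net_config")
  structure(x, class = "soft_model")
}

#' Save / load an aligned model ensemble as JSON
#'
#' @param ensemble a `model_ensemble`.
#' @param path output file.
#' @return `path` invisibly ([save_ensemble()]); the ensemble
#'   ([load_ensemble()]).
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  out <- list(models = lapply(ensemble$models, function(m) {
                x <- unclass(m)
                x$config <- unclass(x$config)
                x
              }),
              state_permutations = ensemble$state_permutations,
              state_feature_matrices = ensemble$state_feature_matrices,
              M = ensemble$M, lag_steps = ensemble$lag_steps,
              frame_interval = ensemble$frame_interval,
              system_label = ensemble$system_label, seed = ensemble$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(seq_len(nrow_safe(x$models)), function(i) NULL)
  # jsonlite may simplify the model list to a data frame; re-read raw
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(raw$models, function(m) {
    rebuild_model(list(
      W = lapply(m$W, function(w) do.call(rbind, lapply(w, unlist))),
      b = lapply(m$b, unlist), dims = unlist(m$dims), M = m$M,
      lag_steps = m$lag_steps, frame_interval = m$frame_interval,
      standardizer = list(mean = unlist(m$standardizer$mean),
                          sd = unlist(m$standardizer$sd)),
      validation_vamp_e = m$validation_vamp_e, init_seed = m$init_seed,
      config = lapply(m$config, unlist), low_score = isTRUE(m$low_score)))
  })
  structure(list(models = models,
                 state_permutations = lapply(raw$state_permutations,
                                             function(p) as.integer(unlist(p))),
                 state_feature_matrices = lapply(raw$state_feature_matrices,
                   function(m) do.call(rbind, lapply(m, unlist))),
                 M = as.integer(raw$M), lag_steps = as.integer(raw$lag_steps),
                 frame_interval = raw$frame_interval,
                 system_label = raw$system_label %||% "",
                 seed = raw$seed %||% NA_integer_),
            class = "model_ensemble")
}

nrow_safe <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Read and featurize a trajectory (PDB topology + DCD coordinates)
#'
#' Requires the bio3d package.  Residues are taken from the topology's
#' protein heavy atoms (optionally restricted to one chain); coordinates
#' come from the PDB models themselves or from a DCD file.
#'
#' @param pdb_file PDB topology (multi-model PDB also serves as
#'   coordinates).
#' @param traj_file optional DCD trajectory.
#' @param mode featurization mode (see [residue_chain()]).
#' @param chain_id optional chain identifier filter.
#' @param frame_interval saved-frame spacing (ns).
#' @return a [trajectory_dataset()] with one trajectory.
#' @export
read_trajectory <- function(pdb_file, traj_file = NULL,
                            mode = "min-heavy-atom", chain_id = NULL,
                            frame_interval = 0.1) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stopf("trajectory ingest requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(pdb_file, multi = TRUE)
  sel <- bio3d::atom.select(pdb, "protein",
                            chain = chain_id %||% unique(pdb$atom$chain),
                            verbose = FALSE)
  atoms <- pdb$atom[sel$atom, , drop = FALSE]
  heavy <- !grepl("^H", trimws(atoms$elety))
  keep <- sel$atom[heavy]
  res_key <- paste(pdb$atom$chain[keep], pdb$atom$resno[keep])
  groups <- split(seq_along(keep), factor(res_key, levels = unique(res_key)))
  ca_local <- which(trimws(pdb$atom$elety[keep]) == "CA")
  ca_atoms <- if (mode == "c-alpha") {
    vapply(groups, function(g) {
      hit <- intersect(g, ca_local)
      if (length(hit) == 0) stopf("a residue lacks a CA atom")
      hit[1]
    }, integer(1))
  } else NULL
  chain <- residue_chain(unname(groups), mode = mode, ca_atoms = ca_atoms)
  xyz <- if (is.null(traj_file)) pdb$xyz else bio3d::read.dcd(traj_file,
                                                              verbose = FALSE)
  xyz <- as.matrix(xyz)
  frames <- lapply(seq_len(nrow(xyz)), function(f) {
    base::matrix(xyz[f, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
  })
  # remap atom groups to the kept-atom submatrix
  feats <- compute_distance_features(frames, chain)
  if (is.null(dim(feats))) feats <- base::matrix(feats, nrow = 1)
  trajectory_dataset(list(feats), frame_interval = frame_interval,
                     pair_index = pair_index(chain$n_residues), mode = mode,
                     system_label = basename(pdb_file))
}
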