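# Run configuration and the pipeline driver.
#
# A run is described by a YAML file (or list).  Defaults follow the
# protocol constants of the method: ensemble of 20 models, 3
# initializations per split, 90/10 train/validation splits, 10,000 frames
# for gradient averaging, 10% subsample for the free-energy surface, and
# alignment threshold T_e = 6.

pipeline_defaults <- function() {
  list(
    seed = 1,
    label = "run",
    systems = list(list(name = "system1", simulate = list())),
    states = 3,
    lag_steps = 5,
    ensemble_size = 20,
    inits_per_split = 3,
    train_fraction = 0.9,
    hidden = c(100, 100, 100, 100),
    epochs = 50,
    batch_size = 1024,
    lr = 1e-3,
    patience = 10,
    feature_mode = "min-heavy-atom",
    gradient_frames = 10000,
    fes_fraction = 0.1,
    fes_lag_steps = NULL,
    threshold = 6,
    constraint_mode = "reversible-nonnegative",
    xi_weighting = "soft")
}

#' Parse, default and validate a run configuration
#'
#' @param raw path to a YAML file, a YAML string, or a list.  Missing keys
#'   take the method's default protocol values; unknown keys are rejected.
#' @return a validated `run_config` list.
#' @export
validate_config <- function(raw = list()) {
  cfg <- if (is.list(raw)) {
    raw
  } else if (length(raw) == 1 && file.exists(raw)) {
    yaml::read_yaml(raw) %||% list()
  } else {
    yaml::yaml.load(paste(raw, collapse = "\n")) %||% list()
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stopf("unknown configuration key '%s'", unknown[1])
  }
  systems_override <- cfg$systems  # replace wholesale, never merge per-entry
  cfg$systems <- NULL
  out <- utils::modifyList(defaults, cfg, keep.null = TRUE)
  if (!is.null(systems_override)) out$systems <- systems_override
  chk <- function(ok, key, what) if (!ok) stopf("config key '%s' %s", key, what)
  chk(is_count(out$states) && out$states >= 2, "states",
      "must be an integer >= 2")
  chk(is_count(out$lag_steps), "lag_steps", "must be a positive integer")
  chk(is_count(out$ensemble_size), "ensemble_size",
      "must be a positive integer")
  chk(is_count(out$inits_per_split), "inits_per_split",
      "must be a positive integer")
  chk(is.numeric(out$train_fraction) && out$train_fraction > 0 &&
        out$train_fraction < 1, "train_fraction",
      "must lie strictly between 0 and 1")
  chk(is.numeric(out$fes_fraction) && out$fes_fraction > 0 &&
        out$fes_fraction <= 1, "fes_fraction", "must lie in (0, 1]")
  chk(is_count(out$gradient_frames), "gradient_frames",
      "must be a positive integer")
  chk(is.numeric(out$threshold) && out$threshold > 0, "threshold",
      "must be positive")
  chk(out$constraint_mode %in% c("reversible-nonnegative", "unconstrained"),
      "constraint_mode", "must be reversible-nonnegative or unconstrained")
  chk(out$xi_weighting %in% c("soft", "hard"), "xi_weighting",
      "must be soft or hard")
  chk(is.list(out$systems) && length(out$systems) >= 1, "systems",
      "must list at least one system")
  for (s in out$systems) {
    chk(!is.null(s$features) || !is.null(s$simulate), "systems",
        "entries need either a 'features' directory or a 'simulate' block")
  }
  structure(out, class = "run_config")
}

stage_message <- function(stage, msg, t0 = NULL) {
  el <- if (is.null(t0)) "" else sprintf(" [%.1f s]",
                                         as.numeric(Sys.time() - t0,
                                                    units = "secs"))
  message(sprintf("[%s] %s%s", stage, msg, el))
}

stage_cached <- function(path, hash) {
  side <- paste0(path, ".prov.json")
  file.exists(path) && file.exists(side) &&
    identical(jsonlite::read_json(side)$hash, hash)
}

stage_mark <- function(path, hash, config_hash, seed) {
  jsonlite::write_json(list(hash = hash, config_hash = config_hash,
                            seed = seed,
                            written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       paste0(path, ".prov.json"), auto_unbox = TRUE)
}

#' Execute the full pipeline described by a configuration
#'
#' Per system: obtain features (simulate the synthetic fixture or load a
#' feature directory), train the aligned model ensemble, estimate kinetics
#' (equilibrium, MFPTs, implied timescale bands), compute per-state
#' ensemble gradient maps and the tICA free-energy surface; with two or
#' more systems, cross-align every pair.  Every artifact carries a
#' provenance sidecar (stage hash, config hash, seed); re-running with the
#' same configuration skips completed stages.
#'
#' @param config a `run_config` (see [validate_config()]), or anything it
#'   accepts.
#' @param run_dir output directory.
#' @return `run_dir`, invisibly; artifacts live underneath it.
#' @export
run_pipeline <- function(config, run_dir) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- object_hash(unclass(cfg))
  yaml::write_yaml(unclass(cfg), file.path(run_dir, "config.yaml"))
  net_cfg <- net_config(hidden = cfg$hidden, lr = cfg$lr,
                        batch_size = cfg$batch_size, epochs = cfg$epochs,
                        patience = cfg$patience,
                        train_fraction = cfg$train_fraction)
  ensembles <- list()
  datasets <- list()
  for (si in seq_along(cfg$systems)) {
    sys <- cfg$systems[[si]]
    name <- sys$name %||% sprintf("system%d", si)
    sdir <- file.path(run_dir, name)
    dir.create(sdir, showWarnings = FALSE)
    seed_sys <- derive_seed(cfg$seed, c(900L, si))

    # --- data stage ---
    t0 <- Sys.time()
    fdir <- file.path(sdir, "features")
    data_hash <- object_hash(list(cfg_hash, sys, "data"))
    if (!is.null(sys$features)) {
      dataset <- read_features(sys$features)
      stage_message("data", sprintf("%s: loaded %d frames from %s", name,
                                    n_frames(dataset), sys$features), t0)
    } else if (stage_cached(file.path(fdir, "features.json"), data_hash)) {
      dataset <- read_features(fdir)
      stage_message("data", sprintf("%s: cache hit (%d frames)", name,
                                    n_frames(dataset)))
    } else {
      sim <- sys$simulate
      spec <- default_fixture(
        n_trajectories = sim$n_trajectories %||% 10,
        frames_per_trajectory = sim$frames_per_trajectory %||% 10000,
        seed = derive_seed(seed_sys, 1L))
      gen <- generate_hmm_dataset(spec)
      dataset <- gen$dataset
      dataset$system_label <- name
      write_features(dataset, fdir)
      jsonlite::write_json(
        list(stationary = gen$truth$stationary, T_true = gen$truth$T_true,
             sigma = gen$truth$sigma),
        file.path(fdir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
      stage_mark(file.path(fdir, "features.json"), data_hash, cfg_hash,
                 seed_sys)
      stage_message("data", sprintf("%s: simulated %d frames", name,
                                    n_frames(dataset)), t0)
    }
    datasets[[name]] <- dataset

    # --- training stage ---
    t0 <- Sys.time()
    epath <- file.path(sdir, "ensemble.json")
    train_hash <- object_hash(list(cfg_hash, data_hash, "train"))
    if (stage_cached(epath, train_hash)) {
      ens <- load_ensemble(epath)
      stage_message("train", sprintf("%s: cache hit (%d models)", name,
                                     length(ens$models)))
    } else {
      ens <- train_ensemble(dataset, M = cfg$states,
                            lag_steps = cfg$lag_steps,
                            N = cfg$ensemble_size,
                            inits_per_split = cfg$inits_per_split,
                            config = net_cfg,
                            seed = derive_seed(seed_sys, 2L),
                            xi_weighting = cfg$xi_weighting)
      save_ensemble(ens, epath)
      stage_mark(epath, train_hash, cfg_hash, seed_sys)
      stage_message("train", sprintf("%s: trained %d models (lag %d steps)",
                                     name, length(ens$models),
                                     cfg$lag_steps), t0)
    }
    ensembles[[name]] <- ens

    # --- kinetics stage ---
    t0 <- Sys.time()
    kpath <- file.path(sdir, "kinetics.json")
    kin_hash <- object_hash(list(train_hash, cfg$constraint_mode, "kinetics"))
    if (!stage_cached(kpath, kin_hash)) {
      pairs <- make_frame_pairs(dataset, cfg$lag_steps)
      ks <- kinetics_summary(ens, pairs, constraint_mode = cfg$constraint_mode)
      jsonlite::write_json(
        list(lag_time = ks$lag_time, pi = ks$pi, mfpt_median = ks$mfpt,
             t2 = ks$t2, T_median = ks$T_median),
        kpath, auto_unbox = TRUE, digits = NA)
      utils::write.csv(ks$mfpt, file.path(sdir, "mfpt_median.csv"),
                       row.names = FALSE)
      stage_mark(kpath, kin_hash, cfg_hash, seed_sys)
      stage_message("kinetics", sprintf("%s: pi median = %s", name,
                                        paste(sprintf("%.3f", ks$pi["50%", ]),
                                              collapse = " ")), t0)
    } else stage_message("kinetics", sprintf("%s: cache hit", name))

    # --- gradients stage ---
    t0 <- Sys.time()
    gpath <- file.path(sdir, "gradients.json")
    grad_hash <- object_hash(list(train_hash, cfg$gradient_frames, "gradients"))
    if (!stage_cached(gpath, grad_hash)) {
      maps <- suppressWarnings(lapply(seq_len(cfg$states), function(m) {
        ensemble_gradient(ens, dataset, m, n_frames = cfg$gradient_frames,
                          seed = derive_seed(seed_sys, c(3L, m)))
      }))
      jsonlite::write_json(
        lapply(maps, function(g) list(state = g$state, g = g$g,
                                      per_residue_abs = g$per_residue_abs,
                                      per_residue_signed = g$per_residue_signed,
                                      n_frames_averaged = g$n_frames_averaged)),
        gpath, auto_unbox = TRUE, digits = NA)
      utils::write.csv(
        data.frame(residue = seq_along(maps[[1]]$per_residue_abs),
                   sapply(maps, `[[`, "per_residue_abs")),
        file.path(sdir, "gradient_profiles.csv"), row.names = FALSE)
      stage_mark(gpath, grad_hash, cfg_hash, seed_sys)
      stage_message("gradients", sprintf("%s: %d state maps", name,
                                         cfg$states), t0)
    } else stage_message("gradients", sprintf("%s: cache hit", name))

    # --- FES stage ---
    t0 <- Sys.time()
    fpath <- file.path(sdir, "fes.json")
    fes_hash <- object_hash(list(data_hash, cfg$fes_fraction, "fes"))
    if (!stage_cached(fpath, fes_hash)) {
      tica <- suppressWarnings(
        fit_tica(dataset, cfg$fes_lag_steps %||% cfg$lag_steps))
      fes <- estimate_fes(tica, subsample_fraction = cfg$fes_fraction,
                          seed = derive_seed(seed_sys, 4L))
      jsonlite::write_json(
        list(eigenvalues = tica$eigenvalues, x = fes$x, y = fes$y,
             bandwidth = fes$bandwidth, n_points = fes$n_points),
        fpath, auto_unbox = TRUE, digits = NA)
      utils::write.csv(fes$F, file.path(sdir, "fes_grid.csv"),
                       row.names = FALSE)
      stage_mark(fpath, fes_hash, cfg_hash, seed_sys)
      stage_message("fes", sprintf("%s: %d x %d grid", name,
                                   fes$grid_size, fes$grid_size), t0)
    } else stage_message("fes", sprintf("%s: cache hit", name))
  }

  # --- cross-system alignment ---
  names_sys <- names(ensembles)
  if (length(ensembles) >= 2) {
    for (a in 1:(length(ensembles) - 1)) {
      for (b in (a + 1):length(ensembles)) {
        t0 <- Sys.time()
        apath <- file.path(run_dir, sprintf("alignment_%s_vs_%s.json",
                                            names_sys[a], names_sys[b]))
        dists1 <- ensemble_state_distributions(ensembles[[a]])
        dists2 <- ensemble_state_distributions(ensembles[[b]])
        C <- cost_matrix(dists1, dists2)
        al <- align_across_systems(C, threshold = cfg$threshold)
        jsonlite::write_json(
          list(system1 = names_sys[a], system2 = names_sys[b], cost = C,
               mapping = al$mapping, pair_costs = al$pair_costs,
               matched = al$matched, threshold = al$threshold,
               swapped = al$swapped),
          apath, auto_unbox = TRUE, digits = NA)
        utils::write.csv(C, file.path(run_dir,
                                      sprintf("cost_%s_vs_%s.csv",
                                              names_sys[a], names_sys[b])),
                         row.names = FALSE)
        stage_message("align-across",
                      sprintf("%s vs %s: %d/%d states matched under T_e = %g",
                              names_sys[a], names_sys[b], sum(al$matched),
                              length(al$matched), cfg$threshold), t0)
      }
    }
  }
  invisible(run_dir)
}

#' Per-state distributions of an ensemble's feature matrices
#'
#' Collects, for each common state m, the per-model average feature vectors
#' (permutation-corrected) into a [state_distribution()] — the object the
#' cross-system alignment compares.
#'
#' @param ensemble an aligned `model_ensemble`.
#' @return list of M [state_distribution()]s.
#' @export
ensemble_state_distributions <- function(ensemble) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  M <- ensemble$M
  lapply(seq_len(M), function(m) {
    atoms <- t(vapply(seq_along(ensemble$models), function(n) {
      node <- which(ensemble$state_permutations[[n]] == m)
      ensemble$state_feature_matrices[[n]][node, ]
    }, numeric(ncol(ensemble$state_feature_matrices[[1]]))))
    state_distribution(atoms, system_label = ensemble$system_label,
                       state_label = m)
  })
}
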