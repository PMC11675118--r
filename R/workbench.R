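# Experiment orchestration: strict flat key-value configuration,
# concentration sweeps with per-matrix / per-trajectory sub-seeds, and
# deterministic output bundles (tidy CSV + JSON manifest).

.config_defaults <- function() {
  list(L = 64L, c = 0, d = 0.5, n_steps = 10000L, n_trajectories = 2L,
       n_matrices = 1L, seed = 1L, points_per_decade = 20L,
       fit_window_short = c(1, 100), fit_window_long = NULL,
       alpha_gate = c(0.9, 1.1), strict_gate = FALSE,
       output_dir = "dllmc-output")
}

# 32-bit FNV-1a over the serialized config; stamps every manifest
.config_hash <- function(config) {
  s <- utf8ToInt(paste(capture.output(str(config)), collapse = "\n"))
  h <- 2166136261
  for (b in s) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Load and validate a run configuration
#'
#' Flat key-value YAML with a strict schema: unknown keys are rejected,
#' missing keys take the documented defaults, and every requested
#' composition is checked for feasibility before any simulation starts.
#' `c` and `d` may be vectors (a concentration sweep).  Configurations at
#' the production scale (`L >= 256`) are marked `cluster_scale` in the
#' manifest.
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::yaml.load_file(path)
  if (is.null(raw)) raw <- list()
  defaults <- .config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    stop("schema error: unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(raw)] <- raw
  cfg$L <- as.integer(cfg$L)
  cfg$n_steps <- as.integer(cfg$n_steps)
  cfg$n_trajectories <- as.integer(cfg$n_trajectories)
  cfg$n_matrices <- as.integer(cfg$n_matrices)
  cfg$seed <- as.integer(cfg$seed)
  cfg$c <- as.numeric(unlist(cfg$c))
  cfg$d <- as.numeric(unlist(cfg$d))
  bad <- c()
  if (cfg$L < 3) bad <- c(bad, "L")
  if (cfg$n_steps < 1) bad <- c(bad, "n_steps")
  if (cfg$n_trajectories < 1) bad <- c(bad, "n_trajectories")
  if (cfg$n_matrices < 1) bad <- c(bad, "n_matrices")
  if (any(cfg$c < 0 | cfg$c > 1)) bad <- c(bad, "c")
  if (any(cfg$d < 0 | cfg$d > 1)) bad <- c(bad, "d")
  if (length(bad) > 0)
    stop("schema error: invalid values for keys: ", paste(bad, collapse = ", "))
  for (cc in cfg$c) for (dd in cfg$d)
    counts_from_concentrations(cfg$L, cc, dd) # infeasibility fails fast here
  cfg$cluster_scale <- cfg$L >= 256
  class(cfg) <- "run_config"
  cfg
}

#' Write a template configuration file
#'
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_config_template <- function(path) {
  d <- .config_defaults()
  d$fit_window_long <- NULL
  yaml::write_yaml(d, path)
  invisible(path)
}

#' Run a configured experiment
#'
#' For every `(c, d)` pair: draws a fresh obstacle matrix per matrix index
#' (sub-seed derived from the master seed), runs the trajectory ensemble on
#' it (per-trajectory sub-seeds; each trajectory re-packs the dimers), and
#' averages the observables over trajectories and matrices.  Emits, per
#' pair, `observables_cD.csv` (MSD, alpha2, cos phi, rho) and a
#' `manifest_cD.json` carrying the full configuration, all sub-seeds and
#' the configuration hash.  Existing outputs for a pair are not recomputed
#' (delete them to re-run); re-running with the same config and seed
#' reproduces the files byte for byte.
#'
#' @param config A `run_config` from [load_config()], or a list of
#'   overrides merged into the defaults.
#' @return Invisible list (one entry per pair) with `observables` (list of
#'   `observable_series`), `fits` (data frame), and `trajectories`.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "run_config")) {
    defaults <- .config_defaults()
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown) > 0)
      stop("schema error: unknown config keys: ", paste(unknown, collapse = ", "))
    defaults[names(config)] <- config
    config <- defaults
    class(config) <- "run_config"
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(unclass(config))
  results <- list()
  pair_idx <- 0
  for (cc in config$c) for (dd in config$d) {
    pair_idx <- pair_idx + 1
    tag <- sprintf("c%0.2f_d%0.2f", cc, dd)
    obs_path <- file.path(config$output_dir, paste0("observables_", tag, ".csv"))
    man_path <- file.path(config$output_dir, paste0("manifest_", tag, ".json"))
    if (file.exists(obs_path)) {
      results[[tag]] <- list(observables = read_observables(obs_path),
                             skipped = TRUE)
      next
    }
    comp <- counts_from_concentrations(config$L, cc, dd)
    trajs <- list()
    seeds <- list()
    for (k in seq_len(config$n_matrices)) {
      mat_seed <- derive_seed(config$seed, 1000 * pair_idx + k)
      set.seed(mat_seed)
      obst <- if (comp$n > 0) sample.int(config$L^2, comp$n) else NULL
      for (j in seq_len(config$n_trajectories)) {
        traj_seed <- derive_seed(mat_seed, j)
        st <- initialize_system(config$L, cc, dd, seed = traj_seed,
                                obstacle_sites = obst)
        trajs[[length(trajs) + 1]] <-
          run_trajectory(st, config$n_steps,
                         points_per_decade = config$points_per_decade)
        seeds[[length(seeds) + 1]] <- list(matrix = k, trajectory = j,
                                           matrix_seed = mat_seed,
                                           trajectory_seed = traj_seed)
      }
    }
    obs <- list()
    obs$msd_solvent <- if (comp$solvent > 0) msd(trajs, "solvent") else NULL
    obs$msd_dimer <- if (comp$m > 0) msd(trajs, "dimer_com") else NULL
    obs$alpha2_solvent <- if (comp$solvent > 0) non_gaussian(trajs, "solvent") else NULL
    obs$alpha2_dimer <- if (comp$m > 0) non_gaussian(trajs, "dimer_com") else NULL
    obs$cos_phi <- if (comp$m > 0) end_to_end_acf(trajs) else NULL
    obs$rho_solvent <- if (comp$solvent > 0) position_acf(trajs, "solvent") else NULL
    obs <- obs[!vapply(obs, is.null, logical(1))]

    fits <- list()
    w_short <- config$fit_window_short
    tmax <- max(trajs[[1]]$times)
    w_long <- if (is.null(config$fit_window_long)) c(tmax / 10, tmax)
              else config$fit_window_long
    for (sp in c("msd_solvent", "msd_dimer")) {
      if (is.null(obs[[sp]])) next
      for (w in list(short = w_short, long = w_long)) {
        f <- tryCatch(fit_diffusion_coefficient(obs[[sp]], w,
                                                gate = config$alpha_gate,
                                                strict = config$strict_gate),
                      error = function(e) NULL)
        if (!is.null(f))
          fits[[length(fits) + 1]] <- data.frame(
            species = sub("msd_", "", sp), c = cc, d = dd,
            window_lo = w[1], window_hi = w[2], alpha = f$alpha, d_w = f$d_w,
            D = f$D, r_squared = f$r_squared, gated = f$gated)
      }
    }
    fits <- if (length(fits) > 0) do.call(rbind, fits) else NULL

    write_observables(obs, obs_path)
    if (!is.null(fits))
      write.csv(fits, file.path(config$output_dir, paste0("fits_", tag, ".csv")),
                row.names = FALSE)
    jsonlite::write_json(
      list(format = "dllmc-manifest", config = unclass(config),
           config_hash = hash, c = cc, d = dd,
           composition = unclass(comp), seeds = seeds,
           cluster_scale = isTRUE(config$cluster_scale)),
      man_path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
    results[[tag]] <- list(observables = obs, fits = fits,
                           trajectories = trajs, skipped = FALSE)
  }
  invisible(results)
}
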