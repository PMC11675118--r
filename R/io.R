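# Text-based containers: a self-describing JSON snapshot for system states,
# a directory container (JSON manifest + CSV datasets) for trajectory
# stores, and tidy CSV for observable series.  All round-trip losslessly.

#' Write a system-state snapshot
#'
#' Self-describing JSON holding the box size, per-site species, dimer
#' table, seed, elapsed time, displacement ledger and realized composition.
#'
#' @param state A `dll_state`.
#' @param path Output file path.
#' @return `path` invisibly.
#' @export
write_state <- function(state, path) {
  payload <- list(
    format = "dllmc-state", version = 1L,
    L = state$L, t = state$t, seed = state$seed,
    species = state$species, obj_at = state$obj_at,
    site_of = state$site_of, obj_species = state$obj_species,
    partner = state$partner, dimers = state$dimers,
    x0 = state$x0, y0 = state$y0, dispx = state$dispx, dispy = state$dispy,
    composition = unclass(state$composition))
  # I(17) significant digits: lossless round-trip for doubles
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Read a system-state snapshot
#'
#' @param path File written by [write_state()].
#' @return A `dll_state`.
#' @export
read_state <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "dllmc-state"))
    stop("not a dllmc state snapshot: ", path)
  comp <- p$composition
  class(comp) <- "system_composition"
  dim_tab <- matrix(as.integer(p$dimers), ncol = 2)
  structure(list(L = as.integer(p$L), species = as.integer(p$species),
                 obj_at = as.integer(p$obj_at), site_of = as.integer(p$site_of),
                 obj_species = as.integer(p$obj_species),
                 partner = as.integer(p$partner), dimers = dim_tab,
                 x0 = as.numeric(p$x0), y0 = as.numeric(p$y0),
                 dispx = as.numeric(p$dispx), dispy = as.numeric(p$dispy),
                 t = as.numeric(p$t),
                 composition = comp,
                 seed = if (is.null(p$seed)) NA_integer_ else as.integer(p$seed)),
            class = "dll_state")
}

#' Plain-text debug dump of a state
#'
#' One line per site: index, axial q, r, species name, object id.
#'
#' @inheritParams write_state
#' @export
write_state_dump <- function(state, path) {
  ax <- site_axial(state$L, seq_len(state$L^2))
  name <- c("SOLVENT", "MER", "OBSTACLE")[state$species + 1L]
  lines <- sprintf("%d %d %d %s %d", seq_len(state$L^2), ax[, "q"], ax[, "r"],
                   name, state$obj_at)
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory store
#'
#' Directory container: `manifest.json` (box, composition, schedule, seed,
#' tallies), `positions.csv` (sample, object, unwrapped x, y, wrapped
#' site), and `end_to_end.csv` (sample, dimer, ex, ey).
#'
#' @param traj A `dll_trajectory`.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(format = "dllmc-trajectory", version = 1L, L = traj$L,
                   times = traj$times,
                   obj_species = traj$obj_species,
                   dimers = traj$dimers,
                   composition = unclass(traj$composition),
                   tallies = list(decades = traj$tallies$decades,
                                  length_hist_found = traj$tallies$length_hist_found,
                                  length_hist_accepted = traj$tallies$length_hist_accepted))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = I(17), auto_unbox = TRUE)
  S <- length(traj$times); n_obj <- ncol(traj$posx)
  pos <- data.frame(sample = rep(seq_len(S), n_obj),
                    object = rep(seq_len(n_obj), each = S),
                    x = as.vector(traj$posx), y = as.vector(traj$posy),
                    site = as.vector(traj$site))
  write.csv(pos, file.path(dir, "positions.csv"), row.names = FALSE)
  m <- ncol(traj$eex)
  ee <- data.frame(sample = rep(seq_len(S), m),
                   dimer = rep(seq_len(m), each = S),
                   ex = as.vector(traj$eex), ey = as.vector(traj$eey))
  write.csv(ee, file.path(dir, "end_to_end.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a trajectory store
#'
#' @param dir Directory written by [write_trajectory()].
#' @return A `dll_trajectory` (without the final engine state).
#' @export
read_trajectory <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(man$format, "dllmc-trajectory"))
    stop("not a dllmc trajectory store: ", dir)
  pos <- read.csv(file.path(dir, "positions.csv"))
  ee <- read.csv(file.path(dir, "end_to_end.csv"))
  S <- length(man$times)
  n_obj <- max(pos$object)
  m <- if (nrow(ee) > 0) max(ee$dimer) else 0L
  comp <- man$composition
  class(comp) <- "system_composition"
  dec <- matrix(as.numeric(man$tallies$decades), ncol = 7)
  colnames(dec) <- c("steps", "loops_found", "two_cycles", "accepted",
                     "rejected_bond_break", "rejected_bond_cross",
                     "objects_moved")
  structure(list(times = as.integer(man$times),
                 posx = matrix(pos$x, nrow = S), posy = matrix(pos$y, nrow = S),
                 site = matrix(pos$site, nrow = S),
                 eex = matrix(ee$ex, nrow = S, ncol = m),
                 eey = matrix(ee$ey, nrow = S, ncol = m),
                 obj_species = as.integer(man$obj_species),
                 dimers = matrix(as.integer(man$dimers), ncol = 2),
                 L = as.integer(man$L), composition = comp, state = NULL,
                 tallies = list(decades = dec,
                                length_hist_found = as.integer(man$tallies$length_hist_found),
                                length_hist_accepted = as.integer(man$tallies$length_hist_accepted))),
            class = "dll_trajectory")
}

#' Write observable series to tidy CSV
#'
#' Columns `time, species, statistic, value, n_ensemble`; several series
#' may be concatenated.
#'
#' @param series An `observable_series` or list of them.
#' @param path Output CSV path.
#' @export
write_observables <- function(series, path) {
  if (inherits(series, "observable_series")) series <- list(series)
  tab <- do.call(rbind, lapply(series, as.data.frame))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read observable series from tidy CSV
#'
#' @param path CSV written by [write_observables()].
#' @return An `observable_series` data frame.
#' @export
read_observables <- function(path) {
  tab <- read.csv(path)
  structure(tab, class = c("observable_series", "data.frame"))
}
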