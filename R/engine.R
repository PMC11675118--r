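#' Assign a random direction field
#'
#' Every non-obstacle site receives an independent uniform direction in
#' `0..5` pointing at one of its six nearest neighbors; obstacle sites get
#' `NA` (they take part in no cooperative loop).
#'
#' @param state A `dll_state`.
#' @return Integer vector of length `L^2` with values `0..5` or `NA`.
#' @export
assign_vectors <- function(state) {
  cpp_gen_field(state)
}

#' Find cooperative loops of a direction field
#'
#' Returns exactly the cycles of the successor map `site -> neighbor along
#' its vector` restricted to non-obstacle sites.  Cycles of length 2
#' (mutual exchange) are rejected by construction and reported separately;
#' sites on no cycle are immobile this step.
#'
#' @param state A `dll_state`.
#' @param field Direction field from [assign_vectors()].
#' @return A list of class `loop_set`: `loops` (list of integer site
#'   cycles, each rotated to start at its smallest site and sorted by that
#'   site), `status` (integer per loop: 0 accepted, 1 rejected bond_break,
#'   2 rejected bond_cross), `two_cycles` (list of rejected 2-cycles).
#'   `find_loops` leaves `status` as computed by the full validator; use
#'   [validate_loops()] for the constraint analysis explicitly.
#' @export
find_loops <- function(state, field) {
  res <- cpp_loops_field(state, as.integer(field))
  structure(res, class = "loop_set")
}

#' Validate cooperative loops against the bond constraints
#'
#' Applies the iterative fixed-point rejection: starting from all candidate
#' loops, any loop whose execution (given the currently accepted set) would
#' leave a dimer's mers at non-nearest-neighbor separation is rejected
#' (`bond_break`), and any loop containing a moving object whose spacetime
#' path crosses a moving dimer bond is rejected (`bond_cross`); sweeps
#' repeat in deterministic ascending loop order until no rejection occurs.
#' The accepted set shrinks monotonically.
#'
#' @inheritParams find_loops
#' @return A `loop_set` (see [find_loops()]) with final `status`.
#' @export
validate_loops <- function(state, field) {
  find_loops(state, field)
}

#' Spacetime crossing test for a moving point and a moving dimer bond
#'
#' All points move by linear interpolation over the step fraction
#' `s` in `[0, 1]`.  Returns `TRUE` iff there is an `s` in `(0, 1]` at
#' which the moving point lies strictly inside the open segment between the
#' interpolated bond endpoints.  Endpoint contact (the point entering a
#' site a mer vacates) is excluded; a zero-length path returns `FALSE`.
#'
#' @param p0,p1 Start and end Cartesian coordinates of the moving point.
#' @param b1_0,b1_1 Start and end coordinates of the first bond endpoint.
#' @param b2_0,b2_1 Start and end coordinates of the second bond endpoint.
#' @return Logical scalar.
#' @export
crossing_test <- function(p0, p1, b1_0, b1_1, b2_0, b2_1) {
  cpp_crossing_test(as.numeric(p0), as.numeric(p1), as.numeric(b1_0),
                    as.numeric(b1_1), as.numeric(b2_0), as.numeric(b2_1))
}

#' Execute one Monte Carlo step
#'
#' Runs assign -> find -> validate -> synchronous cooperative execution:
#' along every accepted loop each object replaces its successor, unwrapped
#' displacement accumulators are updated by the Cartesian unit vector of
#' each hop, and `t` advances by 1.
#'
#' @param state A `dll_state`.
#' @param field Optional fixed direction field (for tests and fixtures);
#'   by default a fresh random field is drawn.
#' @return List with `state` (updated), `loops`, `status`, and `tally`
#'   (loops found/accepted, 2-cycles, rejection counts, objects moved).
#' @export
execute_step <- function(state, field = NULL) {
  if (is.null(field)) field <- assign_vectors(state)
  res <- cpp_step_field(state, as.integer(field))
  st <- res$state
  attributes(st) <- attributes(state)[c("names", "class")]
  st$composition <- state$composition
  st$seed <- state$seed
  res$state <- st
  res
}

#' Logarithmic sampling schedule
#'
#' Approximately `points_per_decade` sample times per decade, always
#' including 0 and `n_steps`.
#'
#' @param n_steps Total number of MC steps.
#' @param points_per_decade Target sampling density (default 20).
#' @return Sorted unique integer vector of sample times in `[0, n_steps]`.
#' @export
log_schedule <- function(n_steps, points_per_decade = 20) {
  if (n_steps < 1) stop("invalid-argument: n_steps must be >= 1")
  ts <- 10^seq(0, log10(n_steps), by = 1 / points_per_decade)
  sort(unique(c(0L, as.integer(round(ts)), as.integer(n_steps))))
}

#' Run a trajectory and record sampled positions
#'
#' Advances the state by `n_steps` Monte Carlo steps, recording unwrapped
#' Cartesian positions, wrapped site indices and dimer end-to-end vectors
#' at the scheduled sample times, plus per-decade loop tallies and
#' loop-length histograms.
#'
#' @param state A `dll_state`.
#' @param n_steps Number of steps (>= 1).
#' @param schedule Sorted integer sample times including 0; defaults to
#'   [log_schedule()].
#' @param points_per_decade Used when `schedule` is `NULL`.
#' @return An object of class `dll_trajectory` with elements `times`,
#'   `posx`, `posy` (samples x objects, unwrapped, lattice units), `site`
#'   (wrapped site identity), `eex`, `eey` (samples x dimers end-to-end
#'   vectors), `obj_species`, `dimers`, `L`, `composition`, `state`
#'   (final), and `tallies`.
#' @export
run_trajectory <- function(state, n_steps, schedule = NULL,
                           points_per_decade = 20) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 1) stop("invalid-argument: n_steps must be >= 1")
  if (is.null(schedule)) schedule <- log_schedule(n_steps, points_per_decade)
  schedule <- sort(unique(as.integer(schedule)))
  if (schedule[1] != 0L) schedule <- c(0L, schedule)
  if (max(schedule) > n_steps)
    stop("invalid-argument: schedule time exceeds n_steps")
  res <- cpp_run(state, n_steps, schedule, state$dimers)
  st <- res$state
  attributes(st) <- attributes(state)[c("names", "class")]
  st$composition <- state$composition
  st$seed <- state$seed
  dec <- res$decade_tally
  colnames(dec) <- c("steps", "loops_found", "two_cycles", "accepted",
                     "rejected_bond_break", "rejected_bond_cross",
                     "objects_moved")
  structure(list(times = schedule, posx = res$posx, posy = res$posy,
                 site = res$site, eex = res$eex, eey = res$eey,
                 obj_species = state$obj_species, dimers = state$dimers,
                 L = state$L, composition = state$composition,
                 state = st,
                 tallies = list(decades = dec,
                                length_hist_found = res$length_hist_found,
                                length_hist_accepted = res$length_hist_accepted)),
            class = "dll_trajectory")
}

#' Run an ensemble of trajectories from independent initializations
#'
#' Convenience wrapper generating `n_trajectories` independent systems at
#' the same composition (fresh obstacle matrix and dimer packing each, or a
#' shared obstacle matrix if `obstacle_sites` is given) and running each
#' for `n_steps`.
#'
#' @inheritParams initialize_system
#' @param n_steps Steps per trajectory.
#' @param n_trajectories Ensemble size.
#' @param schedule,points_per_decade Passed to [run_trajectory()].
#' @param seed Master seed; per-trajectory sub-seeds are derived from it.
#' @return List of `dll_trajectory` objects.
#' @export
run_ensemble <- function(L, c, d, n_steps, n_trajectories, seed,
                         schedule = NULL, points_per_decade = 20) {
  lapply(seq_len(n_trajectories), function(i) {
    st <- initialize_system(L, c, d, seed = derive_seed(seed, i))
    run_trajectory(st, n_steps, schedule = schedule,
                   points_per_decade = points_per_decade)
  })
}

#' @export
print.dll_trajectory <- function(x, ...) {
  cat("dll_trajectory: L =", x$L, ", samples =", length(x$times),
      ", final t =", max(x$times), "\n")
  invisible(x)
}

#' @export
print.loop_set <- function(x, ...) {
  cat("loop_set:", length(x$loops), "loops (",
      sum(x$status == 0), "accepted,", sum(x$status == 1), "bond_break,",
      sum(x$status == 2), "bond_cross ),",
      length(x$two_cycles), "two-cycles\n")
  invisible(x)
}
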