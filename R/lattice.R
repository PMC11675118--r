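#' Triangular-lattice geometry with periodic boundaries
#'
#' Builds the geometry of an `L` x `L` rhombic periodic box on the
#' two-dimensional triangular lattice.  Sites are addressed by axial
#' coordinates `(q, r)` with `0 <= q, r < L` and site index
#' `q + r*L + 1`; the Cartesian embedding is `x = q + r/2`,
#' `y = r*sqrt(3)/2` with lattice constant 1.  The six neighbor offsets are
#' `(1,0), (0,1), (-1,1), (-1,0), (0,-1), (1,-1)` (directions `0..5`), so
#' direction `k` and `(k+3) %% 6` are inverses.
#'
#' @param L Box edge in sites; must be at least 3 (no cooperative loop of
#'   length >= 3 fits otherwise).
#' @return An object of class `tri_lattice` with elements `L`, `n_sites`,
#'   `offsets` (6 x 2 integer matrix of axial offsets), `unit_vectors`
#'   (6 x 2 Cartesian unit displacement matrix), and `nbr`
#'   (`n_sites` x 6 neighbor-index matrix, 1-based).
#' @export
build_lattice <- function(L) {
  L <- as.integer(L)
  if (length(L) != 1L || is.na(L) || L < 3L)
    stop("invalid-argument: L must be a single integer >= 3")
  offsets <- cbind(q = c(1L, 0L, -1L, -1L, 0L, 1L),
                   r = c(0L, 1L, 1L, 0L, -1L, -1L))
  uv <- cbind(x = offsets[, 1] + offsets[, 2] / 2,
              y = offsets[, 2] * sqrt(3) / 2)
  q <- rep(0:(L - 1L), times = L)
  r <- rep(0:(L - 1L), each = L)
  nbr <- matrix(0L, nrow = L * L, ncol = 6L)
  for (k in 1:6) {
    nbr[, k] <- ((q + offsets[k, 1]) %% L) + ((r + offsets[k, 2]) %% L) * L + 1L
  }
  structure(list(L = L, n_sites = L * L, offsets = offsets,
                 unit_vectors = uv, nbr = nbr),
            class = "tri_lattice")
}

#' Axial coordinates of site indices
#'
#' @param lattice A [build_lattice()] object (or an integer `L`).
#' @param site 1-based site indices.
#' @return Integer matrix with columns `q`, `r`.
#' @export
site_axial <- function(lattice, site) {
  L <- if (inherits(lattice, "tri_lattice")) lattice$L else as.integer(lattice)
  s <- as.integer(site) - 1L
  cbind(q = s %% L, r = s %/% L)
}

#' Cartesian coordinates of site indices
#'
#' @inheritParams site_axial
#' @return Numeric matrix with columns `x`, `y` (lattice-constant units).
#' @export
site_xy <- function(lattice, site) {
  a <- site_axial(lattice, site)
  cbind(x = a[, "q"] + a[, "r"] / 2, y = a[, "r"] * sqrt(3) / 2)
}

#' Minimal-image Cartesian displacement between two sites
#'
#' @inheritParams site_axial
#' @param from,to 1-based site indices (scalars).
#' @return Numeric vector `c(x, y)` of the shortest periodic image of
#'   `to - from`.
#' @export
minimal_image <- function(lattice, from, to) {
  L <- if (inherits(lattice, "tri_lattice")) lattice$L else as.integer(lattice)
  cpp_mindisp(L, as.integer(from), as.integer(to))
}

#' Object counts realizing requested concentrations
#'
#' The obstacle concentration is `c = n/L^2` and the dimer concentration is
#' `d = 2m/L^2` (fraction of sites covered by mers).  Counts are rounded to
#' the nearest integer (ties to even, the R default) and the realized
#' concentrations are reported alongside the requested ones.
#'
#' @param L Box edge in sites.
#' @param c Requested obstacle concentration in `[0, 1]`.
#' @param d Requested dimer concentration in `[0, 1]`.
#' @return A list of class `system_composition` with `L`, requested and
#'   realized `c` and `d`, counts `n` (obstacles), `m` (dimers), and
#'   `solvent`.
#' @export
counts_from_concentrations <- function(L, c, d) {
  L <- as.integer(L)
  if (c < 0 || d < 0 || c > 1 || d > 1)
    stop("invalid-argument: concentrations must be in [0, 1]")
  N <- L * L
  n <- as.integer(round(c * N))
  m <- as.integer(round(d * N / 2))
  if (n + 2L * m > N)
    stop("infeasible-composition: n + 2m exceeds the number of lattice sites")
  structure(list(L = L, c_requested = c, d_requested = d,
                 n = n, m = m, solvent = N - n - 2L * m,
                 c_realized = n / N, d_realized = 2 * m / N),
            class = "system_composition")
}

#' Initialize a lattice-liquid system
#'
#' Places `n = round(c*L^2)` immobile obstacles uniformly at random, then
#' `m = round(d*L^2/2)` dimers by random sequential adsorption (RSA) on
#' edges whose both endpoints are free.  If RSA stalls before reaching the
#' target count (which it must at high coverage, since RSA jams), a
#' vacancy-diffusion repair stage flips dimers so vacancies random-walk
#' until two become adjacent and an additional dimer is placed.  Remaining
#' sites are filled with solvent.  The whole procedure restarts with the
#' running RNG stream up to `max_restarts` times before raising an
#' infeasible-packing error.
#'
#' @inheritParams counts_from_concentrations
#' @param seed Optional integer seed (`set.seed` is called when given);
#'   omit to use the current RNG stream.
#' @param obstacle_sites Optional fixed obstacle matrix (1-based site
#'   indices, length `round(c*L^2)`); when given, only the dimer packing is
#'   random, so a trajectory ensemble can share one obstacle matrix.
#' @param rsa_factor RSA attempt budget per dimer (default 1000).
#' @param repair_factor Vacancy-move budget per lattice site (default 2000).
#' @param max_restarts Restart cap (default 20).
#' @return An object of class `dll_state`: full lattice occupancy
#'   (`species`, `obj_at`), per-object bookkeeping (`site_of`,
#'   `obj_species`, `partner`, `dimers` table, initial Cartesian positions
#'   `x0`, `y0`, unwrapped displacement accumulators `dispx`, `dispy`),
#'   elapsed time `t` in MC steps, and the realized composition.
#' @export
initialize_system <- function(L, c, d, seed = NULL, obstacle_sites = NULL,
                              rsa_factor = 1000, repair_factor = 2000,
                              max_restarts = 20L) {
  comp <- counts_from_concentrations(L, c, d)
  if (!is.null(seed)) set.seed(as.integer(seed))
  st <- cpp_init(comp$L, comp$n, comp$m, rsa_factor, repair_factor,
                 as.integer(max_restarts),
                 if (is.null(obstacle_sites)) integer(0)
                 else as.integer(obstacle_sites))
  st$composition <- comp
  st$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  class(st) <- "dll_state"
  st
}

#' Build a system from an explicit layout
#'
#' Deterministic constructor used for fixtures and tests: obstacles and
#' dimers are placed at the given sites, everything else becomes solvent.
#'
#' @param L Box edge.
#' @param obstacle_sites Integer vector of 1-based site indices.
#' @param dimer_sites Two-column integer matrix; each row is a pair of
#'   nearest-neighbor sites occupied by one dimer.
#' @return A `dll_state`.
#' @export
system_from_layout <- function(L, obstacle_sites = integer(0),
                               dimer_sites = NULL) {
  lat <- build_lattice(L)
  N <- lat$n_sites
  species <- rep(.SOLVENT, N)
  species[obstacle_sites] <- .OBSTACLE
  if (is.null(dimer_sites)) dimer_sites <- matrix(integer(0), ncol = 2)
  dimer_sites <- matrix(as.integer(dimer_sites), ncol = 2)
  m <- nrow(dimer_sites)
  if (m > 0) {
    for (i in seq_len(m)) {
      s1 <- dimer_sites[i, 1]; s2 <- dimer_sites[i, 2]
      if (!(s2 %in% lat$nbr[s1, ]))
        stop("invalid-argument: dimer sites must be nearest neighbors")
      if (any(species[c(s1, s2)] != .SOLVENT))
        stop("invalid-argument: dimer sites overlap other objects")
      species[c(s1, s2)] <- .MER
    }
  }
  n_obj <- N
  site_of <- integer(n_obj); obj_species <- integer(n_obj)
  partner <- integer(n_obj); obj_at <- integer(N)
  dimers <- matrix(0L, nrow = m, ncol = 2)
  nxt <- 1L
  for (i in seq_len(m)) {
    o1 <- nxt; o2 <- nxt + 1L; nxt <- nxt + 2L
    site_of[c(o1, o2)] <- dimer_sites[i, ]
    obj_species[c(o1, o2)] <- .MER
    partner[o1] <- o2; partner[o2] <- o1
    obj_at[dimer_sites[i, ]] <- c(o1, o2)
    dimers[i, ] <- c(o1, o2)
  }
  for (s in seq_len(N)) {
    if (species[s] == .MER) next
    site_of[nxt] <- s
    obj_species[nxt] <- species[s]
    obj_at[s] <- nxt
    nxt <- nxt + 1L
  }
  xy <- site_xy(lat, site_of)
  comp <- counts_from_concentrations(L, length(obstacle_sites) / N, 2 * m / N)
  structure(list(L = L, species = as.integer(species), obj_at = obj_at,
                 site_of = site_of, obj_species = obj_species,
                 partner = partner, dimers = dimers,
                 x0 = xy[, "x"], y0 = xy[, "y"],
                 dispx = numeric(n_obj), dispy = numeric(n_obj), t = 0,
                 composition = comp, seed = NA_integer_),
            class = "dll_state")
}

#' Validate all structural invariants of a system state
#'
#' Walks the lattice and re-derives every invariant independently of the
#' engine: full single occupancy, consistency of the site/object maps,
#' species counts against the composition, nearest-neighbor adjacency of
#' every dimer, and zero accumulated displacement for obstacles.
#'
#' @param state A `dll_state`.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_state <- function(state) {
  L <- state$L; N <- L * L
  lat <- build_lattice(L)
  if (length(state$species) != N) stop("species vector has wrong length")
  if (any(sort(state$site_of) != seq_len(N)))
    stop("occupancy violated: site_of is not a permutation of sites")
  if (any(state$obj_at[state$site_of] != seq_along(state$site_of)))
    stop("obj_at and site_of are inconsistent")
  if (any(state$species[state$site_of] != state$obj_species))
    stop("site species disagree with object species")
  comp <- state$composition
  if (!is.null(comp)) {
    cnt <- tabulate(state$obj_species + 1L, nbins = 3L)
    if (cnt[1] != comp$solvent || cnt[2] != 2L * comp$m || cnt[3] != comp$n)
      stop("species counts disagree with composition")
  }
  if (nrow(state$dimers) > 0) {
    for (i in seq_len(nrow(state$dimers))) {
      s1 <- state$site_of[state$dimers[i, 1]]
      s2 <- state$site_of[state$dimers[i, 2]]
      if (!(s2 %in% lat$nbr[s1, ]))
        stop("dimer ", i, " mers are not nearest neighbors")
    }
  }
  obst <- state$obj_species == .OBSTACLE
  if (any(abs(state$dispx[obst]) > 1e-12) || any(abs(state$dispy[obst]) > 1e-12))
    stop("an obstacle has accumulated displacement")
  invisible(TRUE)
}

#' @export
print.dll_state <- function(x, ...) {
  comp <- x$composition
  cat("dll_state: L =", x$L, " t =", x$t, "\n")
  if (!is.null(comp))
    cat(sprintf("  obstacles n = %d (c = %.4f), dimers m = %d (d = %.4f), solvent = %d\n",
                comp$n, comp$c_realized, comp$m, comp$d_realized, comp$solvent))
  invisible(x)
}

#' @export
print.system_composition <- function(x, ...) {
  cat(sprintf("composition L = %d: n = %d (c = %.4f), m = %d (d = %.4f), solvent = %d\n",
              x$L, x$n, x$c_realized, x$m, x$d_realized, x$solvent))
  invisible(x)
}
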