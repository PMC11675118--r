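# Independent brute-force oracles, deliberately implemented from scratch in
# plain R (no reuse of the engine's code path): functional-graph cycle
# enumeration, exhaustive loop rejection with a sampling/root-refinement
# crossing predicate, a flood-fill wrapping detector for percolation, and
# an ideal-walk trajectory builder.

.OFFS <- cbind(q = c(1L, 0L, -1L, -1L, 0L, 1L),
               r = c(0L, 1L, 1L, 0L, -1L, -1L))
.UVEC <- cbind(x = .OFFS[, 1] + .OFFS[, 2] / 2,
               y = .OFFS[, 2] * sqrt(3) / 2)

oracle_succ <- function(state, field) {
  L <- state$L; N <- L * L
  q <- (seq_len(N) - 1L) %% L
  r <- (seq_len(N) - 1L) %/% L
  succ <- rep(NA_integer_, N)
  for (s in seq_len(N)) {
    k <- field[s]
    if (is.na(k) || state$species[s] == 2L) next
    succ[s] <- ((q[s] + .OFFS[k + 1L, 1]) %% L) +
      ((r[s] + .OFFS[k + 1L, 2]) %% L) * L + 1L
  }
  succ
}

# all cycles of the successor map; returns list(loops, twos), each loop
# rotated to start at its smallest site, loops sorted by that site
oracle_cycles <- function(state, field) {
  succ <- oracle_succ(state, field)
  N <- length(succ)
  visited <- rep(FALSE, N)
  loops <- list(); twos <- list()
  for (s0 in seq_len(N)) {
    if (visited[s0] || is.na(succ[s0])) next
    posmap <- integer(N)
    path <- integer(0)
    cur <- s0
    repeat {
      if (is.na(succ[cur]) || visited[cur]) break # obstacle or known territory
      if (posmap[cur] > 0L) {
        cyc <- path[posmap[cur]:length(path)]
        i <- which.min(cyc)
        cyc <- c(cyc[i:length(cyc)], cyc[seq_len(i - 1L)])
        if (length(cyc) >= 3L) loops[[length(loops) + 1L]] <- cyc
        else twos[[length(twos) + 1L]] <- cyc
        break
      }
      posmap[cur] <- length(path) + 1L
      path <- c(path, cur)
      cur <- succ[cur]
    }
    visited[path] <- TRUE
  }
  ord <- order(vapply(loops, function(x) x[1], 0L))
  list(loops = loops[ord], twos = twos)
}

oracle_mindisp <- function(L, a, b) {
  dq <- (b - 1L) %% L - (a - 1L) %% L
  dr <- (b - 1L) %/% L - (a - 1L) %/% L
  best <- Inf; out <- c(0, 0)
  for (i in -1:1) for (j in -1:1) {
    x <- (dq + i * L) + (dr + j * L) / 2
    y <- (dr + j * L) * sqrt(3) / 2
    if (x * x + y * y < best) { best <- x * x + y * y; out <- c(x, y) }
  }
  out
}

# crossing predicate by dense sampling of the signed area plus uniroot
# refinement of every sign bracket; independent of the closed-form solver
oracle_crossing <- function(p0, dp, b1, d1, b2, d2, ngrid = 400) {
  if (sum(dp^2) < 1e-18) return(FALSE)
  f <- function(s) {
    ux <- b2[1] + s * d2[1] - b1[1] - s * d1[1]
    uy <- b2[2] + s * d2[2] - b1[2] - s * d1[2]
    wx <- p0[1] + s * dp[1] - b1[1] - s * d1[1]
    wy <- p0[2] + s * dp[2] - b1[2] - s * d1[2]
    ux * wy - uy * wx
  }
  interior <- function(s) {
    ux <- b2[1] + s * d2[1] - b1[1] - s * d1[1]
    uy <- b2[2] + s * d2[2] - b1[2] - s * d1[2]
    wx <- p0[1] + s * dp[1] - b1[1] - s * d1[1]
    wy <- p0[2] + s * dp[2] - b1[2] - s * d1[2]
    uu <- ux^2 + uy^2
    if (uu < 1e-9) return(FALSE)
    tt <- (wx * ux + wy * uy) / uu
    tt > 1e-7 && tt < 1 - 1e-7
  }
  ss <- seq(0, 1, length.out = ngrid)
  fv <- f(ss)
  if (max(abs(fv)) < 1e-12) return(FALSE) # collinear throughout; no pass
  brackets <- which(abs(fv[-ngrid]) < 1e-12 | fv[-ngrid] * fv[-1] < 0)
  for (i in brackets) {
    root <- if (abs(fv[i]) < 1e-12) ss[i]
            else uniroot(f, c(ss[i], ss[i + 1]), tol = 1e-12)$root
    if (root > 1e-9 && root <= 1 && interior(root)) return(TRUE)
  }
  if (abs(fv[ngrid]) < 1e-12 && interior(1)) return(TRUE)
  # an interior tangency can sit between grid points with no sign change:
  # refine around the minimum |f|
  i <- which.min(abs(fv))
  lo <- max(ss[i] - 1 / ngrid, 0); hi <- min(ss[i] + 1 / ngrid, 1)
  op <- optimize(function(s) abs(f(s)), c(lo, hi))
  if (op$objective < 1e-12 && op$minimum > 1e-9 && interior(op$minimum))
    return(TRUE)
  FALSE
}

# exhaustive validation to the fixed point: same documented semantics as the
# engine (ascending loop order, monotone rejection, break checked before
# crossing) but with no spatial pruning and the sampling-based predicate
oracle_validate <- function(state, field) {
  cyc <- oracle_cycles(state, field)
  loops <- cyc$loops
  K <- length(loops)
  L <- state$L; N <- L * L
  loop_of <- rep(NA_integer_, N)
  for (j in seq_len(K)) loop_of[loops[[j]]] <- j
  status <- integer(K)
  m <- nrow(state$dimers)
  repeat {
    changed <- FALSE
    for (j in seq_len(K)) {
      if (status[j] != 0L) next
      reason <- 0L
      # every dimer, exhaustively
      for (i in seq_len(m)) {
        o1 <- state$dimers[i, 1]; o2 <- state$dimers[i, 2]
        s1 <- state$site_of[o1]; s2 <- state$site_of[o2]
        l1 <- loop_of[s1]; l2 <- loop_of[s2]
        mv1 <- !is.na(l1) && status[l1] == 0L
        mv2 <- !is.na(l2) && status[l2] == 0L
        in_j <- (identical(l1, j) && mv1) || (identical(l2, j) && mv2)
        if (!in_j) next
        p1 <- oracle_mindisp(L, s1, s1) + if (mv1) .UVEC[field[s1] + 1L, ] else c(0, 0)
        p2 <- oracle_mindisp(L, s1, s2) + if (mv2) .UVEC[field[s2] + 1L, ] else c(0, 0)
        if (abs(sum((p2 - p1)^2) - 1) > 1e-6) { reason <- 1L; break }
      }
      if (reason == 0L && m > 0) {
        for (s in loops[[j]]) {
          o <- state$obj_at[s]
          for (i in seq_len(m)) {
            o1 <- state$dimers[i, 1]; o2 <- state$dimers[i, 2]
            if (o == o1 || o == o2) next
            s1 <- state$site_of[o1]; s2 <- state$site_of[o2]
            l1 <- loop_of[s1]; l2 <- loop_of[s2]
            mv1 <- !is.na(l1) && status[l1] == 0L
            mv2 <- !is.na(l2) && status[l2] == 0L
            if (!mv1 && !mv2) next
            b1 <- oracle_mindisp(L, s, s1)
            b2 <- b1 + oracle_mindisp(L, s1, s2)
            if (oracle_crossing(c(0, 0), .UVEC[field[s] + 1L, ],
                                b1, if (mv1) .UVEC[field[s1] + 1L, ] else c(0, 0),
                                b2, if (mv2) .UVEC[field[s2] + 1L, ] else c(0, 0))) {
              reason <- 2L
              break
            }
          }
          if (reason != 0L) break
        }
      }
      if (reason != 0L) { status[j] <- reason; changed <- TRUE }
    }
    if (!changed) break
  }
  list(loops = loops, status = status, twos = cyc$twos)
}

# flood-fill wrapping detector: BFS assigns unwrapped axial coordinates; a
# revisit with different unwrapped coordinates means the cluster wraps
oracle_wraps <- function(L, open) {
  N <- L * L
  seen <- rep(FALSE, N)
  uq <- ur <- rep(NA_real_, N)
  for (s0 in seq_len(N)) {
    if (!open[s0] || seen[s0]) next
    queue <- s0; seen[s0] <- TRUE; uq[s0] <- 0; ur[s0] <- 0
    while (length(queue) > 0) {
      s <- queue[1]; queue <- queue[-1]
      q <- (s - 1L) %% L; r <- (s - 1L) %/% L
      for (k in 1:6) {
        s2 <- ((q + .OFFS[k, 1]) %% L) + ((r + .OFFS[k, 2]) %% L) * L + 1L
        if (!open[s2]) next
        nq <- uq[s] + .OFFS[k, 1]; nr <- ur[s] + .OFFS[k, 2]
        if (!seen[s2]) {
          seen[s2] <- TRUE; uq[s2] <- nq; ur[s2] <- nr
          queue <- c(queue, s2)
        } else if (uq[s2] != nq || ur[s2] != nr) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

# ideal unconstrained triangular-lattice walk packaged as a dll_trajectory
# (surrogate for testing the observables layer in isolation)
ideal_walk_trajectory <- function(n_walkers, n_steps, times = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(times)) times <- 0:n_steps
  posx <- matrix(0, length(times), n_walkers)
  posy <- matrix(0, length(times), n_walkers)
  x <- y <- numeric(n_walkers)
  ti <- 1L
  for (step in 0:n_steps) {
    if (step == times[ti]) {
      posx[ti, ] <- x; posy[ti, ] <- y
      ti <- ti + 1L
      if (ti > length(times)) break
    }
    k <- sample.int(6, n_walkers, replace = TRUE)
    x <- x + .UVEC[k, 1]
    y <- y + .UVEC[k, 2]
  }
  structure(list(times = as.integer(times), posx = posx, posy = posy,
                 site = matrix(1L, length(times), n_walkers),
                 eex = matrix(0, length(times), 0),
                 eey = matrix(0, length(times), 0),
                 obj_species = rep(0L, n_walkers),
                 dimers = matrix(integer(0), ncol = 2), L = 10000L,
                 composition = NULL, state = NULL,
                 tallies = list(decades = matrix(0, 1, 7,
                                  dimnames = list(NULL, c("steps", "loops_found",
                                    "two_cycles", "accepted", "rejected_bond_break",
                                    "rejected_bond_cross", "objects_moved"))),
                                length_hist_found = integer(257),
                                length_hist_accepted = integer(257))),
            class = "dll_trajectory")
}

# build a minimal fake trajectory from explicit matrices (tests only)
fake_trajectory <- function(times, posx, posy, site = NULL, eex = NULL,
                            eey = NULL, obj_species = NULL, dimers = NULL) {
  n <- ncol(posx)
  if (is.null(site)) site <- matrix(1L, nrow(posx), n)
  if (is.null(eex)) { eex <- matrix(0, nrow(posx), 0); eey <- eex }
  if (is.null(obj_species)) obj_species <- rep(0L, n)
  if (is.null(dimers)) dimers <- matrix(integer(0), ncol = 2)
  structure(list(times = times, posx = posx, posy = posy, site = site,
                 eex = eex, eey = eey, obj_species = obj_species,
                 dimers = dimers, L = 64L, composition = NULL, state = NULL,
                 tallies = NULL),
            class = "dll_trajectory")
}
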