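# Deterministic small fixtures: hand-constructed direction fields covering
# the five canonical single-step situations (mutual exchange, unreachable
# target, bond break, bond crossing, successful cooperative loop with an
# intact dimer), plus a fixed-seed golden run.  Sites are written below in
# axial (q, r); index = q + r*L + 1.

.ax <- function(L, q, r) (q %% L) + (r %% L) * L + 1L

#' Build the deterministic fixture bundle
#'
#' Small systems (L = 4, 6, 16) and direction fields with known outcomes,
#' used by the test suite and reproducible from the stored seed.
#'
#' Variants: (1) two elements try to exchange places (2-cycle, never
#' executed); (2) every path dead-ends in an obstacle, so no loop exists;
#' (3) a loop moves one mer to sqrt(3) separation from its stationary
#' partner (bond_break); (4) a solvent molecule passes between the two
#' mers of a translating dimer (bond_cross); (5) a 3-loop carrying both
#' mers of a dimer executes and the bond survives.
#'
#' @param seed Seed for the golden-run fixture (default 20260101).
#' @return Named list of fixtures; each variant holds `state`, `field` and
#'   an `expect` string.
#' @export
make_fixtures <- function(seed = 20260101) {
  L <- 4L
  fx <- list()

  # variant 1: mutual exchange between (0,0) and (1,0); everything else
  # chains into the pair or into row 0 without forming cycles
  f <- rep(4L, L * L)                      # default: point down (0,-1)
  f[.ax(L, 0, 0)] <- 0L                    # (0,0) -> (1,0)
  f[.ax(L, 1, 0)] <- 3L                    # (1,0) -> (0,0)
  f[.ax(L, 2, 0)] <- 3L                    # chain toward the pair
  f[.ax(L, 3, 0)] <- 0L                    # wraps to (0,0)
  fx$variant1 <- list(state = system_from_layout(L), field = f,
                      expect = "one 2-cycle, zero loops, zero moves")

  # variant 2: obstacle at (0,0); all chains dead-end there
  f <- rep(4L, L * L)
  f[.ax(L, 1, 0)] <- 3L; f[.ax(L, 2, 0)] <- 3L; f[.ax(L, 3, 0)] <- 3L
  f[.ax(L, 0, 0)] <- NA_integer_
  fx$variant2 <- list(state = system_from_layout(L, obstacle_sites = .ax(L, 0, 0)),
                      field = f,
                      expect = "no loops at all: every target is unreachable")

  # variant 3: dimer on (0,0)-(1,0); triangle (0,0)->(3,1)->(3,0)->(0,0)
  # moves the first mer to sqrt(3) separation -> bond_break
  f <- rep(4L, L * L)
  f[.ax(L, 0, 0)] <- 2L                    # (0,0) -> (-1,1) = (3,1)
  f[.ax(L, 3, 1)] <- 4L                    # (3,1) -> (3,0)
  f[.ax(L, 3, 0)] <- 0L                    # (3,0) -> (0,0)
  f[.ax(L, 1, 0)] <- 3L                    # partner chains in, stays immobile
  f[.ax(L, 2, 0)] <- 3L
  st <- system_from_layout(L, dimer_sites = rbind(c(.ax(L, 0, 0), .ax(L, 1, 0))))
  fx$variant3 <- list(state = st, field = f,
                      expect = "single 3-loop rejected with reason bond_break")

  # variant 4: dimer on (0,0)-(0,1) translating right inside a 6-loop while
  # the solvent at (1,0) cuts between the moving mers -> bond_cross
  f <- rep(4L, L * L)
  f[.ax(L, 0, 0)] <- 0L                    # b1 (0,0) -> (1,0)
  f[.ax(L, 1, 0)] <- 2L                    # solvent (1,0) -> (0,1)
  f[.ax(L, 0, 1)] <- 0L                    # b2 (0,1) -> (1,1)
  f[.ax(L, 1, 1)] <- 5L                    # (1,1) -> (2,0)
  f[.ax(L, 2, 0)] <- 0L                    # (2,0) -> (3,0)
  f[.ax(L, 3, 0)] <- 0L                    # (3,0) -> (0,0) closes the loop
  st <- system_from_layout(L, dimer_sites = rbind(c(.ax(L, 0, 0), .ax(L, 0, 1))))
  fx$variant4 <- list(state = st, field = f,
                      expect = "single 6-loop rejected with reason bond_cross")

  # variant 5: triangle (0,0)->(1,0)->(0,1)->(0,0) carrying both mers of
  # one dimer plus one solvent; the bond maps onto another triangle edge
  f <- rep(4L, L * L)
  f[.ax(L, 0, 0)] <- 0L                    # b1 -> (1,0)
  f[.ax(L, 1, 0)] <- 2L                    # b2 -> (0,1)
  f[.ax(L, 0, 1)] <- 4L                    # solvent -> (0,0)
  f[.ax(L, 2, 0)] <- 3L
  f[.ax(L, 3, 0)] <- 0L                    # dead chain into the triangle
  st <- system_from_layout(L, dimer_sites = rbind(c(.ax(L, 0, 0), .ax(L, 1, 0))))
  fx$variant5 <- list(state = st, field = f,
                      expect = "3-loop accepted; dimer bond survives the move")

  # uniform field: every site direction 0 -> L disjoint winding row loops
  fx$uniform_rows <- list(state = system_from_layout(L),
                          field = rep(0L, L * L),
                          expect = "4 loops of length 4 (torus-winding rows)")

  # golden fixture: fixed-seed run, regenerates bit-identically
  st <- initialize_system(16L, c = 0.12, d = 0.5, seed = seed)
  fx$golden <- list(seed = seed, L = 16L, c = 0.12, d = 0.5, n_steps = 50L,
                    make = function() {
                      s0 <- initialize_system(16L, c = 0.12, d = 0.5, seed = seed)
                      set.seed(derive_seed(seed, 1))
                      run_trajectory(s0, 50L, points_per_decade = 10)
                    })
  fx
}
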