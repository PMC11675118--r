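# Direction fields, loop finding, constraint validation and single-step
# execution, checked against hand-constructed fixtures and the independent
# R oracle.

test_that("direction fields cover only mobile sites, uniformly", {
  st <- system_from_layout(4, obstacle_sites = 1:16)
  expect_true(all(is.na(assign_vectors(st))))
  st <- system_from_layout(8)
  set.seed(4); f1 <- assign_vectors(st)
  set.seed(4); f2 <- assign_vectors(st)
  expect_identical(f1, f2)
  # ~1e5 draws pooled over sites: each direction frequency 1/6 +/- 0.01
  st <- system_from_layout(32)
  set.seed(12)
  draws <- unlist(lapply(1:100, function(i) assign_vectors(st)))
  freq <- tabulate(draws + 1L, nbins = 6) / length(draws)
  expect_true(all(abs(freq - 1 / 6) < 0.01))
})

test_that("find_loops returns exactly the >=3 cycles of the successor map", {
  fx <- make_fixtures()
  # uniform field: L winding row-loops of length L, matching the oracle
  ls <- find_loops(fx$uniform_rows$state, fx$uniform_rows$field)
  expect_length(ls$loops, 4L)
  expect_true(all(lengths(ls$loops) == 4L))
  orc <- oracle_cycles(fx$uniform_rows$state, fx$uniform_rows$field)
  expect_identical(lapply(ls$loops, as.integer), orc$loops)
  # mutual exchange: a 2-cycle is recorded but never becomes a loop
  ls <- find_loops(fx$variant1$state, fx$variant1$field)
  expect_length(ls$loops, 0L)
  expect_length(ls$two_cycles, 1L)
  # every chain dead-ends in an obstacle: no loop at all
  ls <- find_loops(fx$variant2$state, fx$variant2$field)
  expect_length(ls$loops, 0L)
  expect_length(ls$two_cycles, 0L)
  # an isolated triangle is one loop of length 3
  ls <- find_loops(fx$variant5$state, fx$variant5$field)
  expect_length(ls$loops, 1L)
  expect_length(ls$loops[[1]], 3L)
})

test_that("loop validation enforces bond rigidity and crossing exclusion", {
  fx <- make_fixtures()
  # a mer pulled to sqrt(3) separation: bond_break
  ls <- validate_loops(fx$variant3$state, fx$variant3$field)
  expect_identical(as.integer(ls$status), 1L)
  # solvent cutting between the mers of a translating dimer: bond_cross
  ls <- validate_loops(fx$variant4$state, fx$variant4$field)
  expect_identical(as.integer(ls$status), 2L)
  # 3-loop carrying a whole dimer: the bond maps onto another triangle
  # edge and the loop is accepted
  ls <- validate_loops(fx$variant5$state, fx$variant5$field)
  expect_identical(as.integer(ls$status), 0L)
})

test_that("bond-break rejection propagates monotonically to a fixed point", {
  # dimer on (0,0)-(1,0) of an L=6 box; loop A would drag the first mer to
  # sqrt(3) separation (with both loops running), loop B alone also breaks
  # the bond; both must end rejected
  L <- 6L
  ax <- function(q, r) (q %% L) + (r %% L) * L + 1L
  st <- system_from_layout(L, dimer_sites = rbind(c(ax(0, 0), ax(1, 0))))
  f <- rep(4L, L * L)
  f[ax(0, 0)] <- 2L; f[ax(5, 1)] <- 4L; f[ax(5, 0)] <- 0L        # loop A
  f[ax(1, 0)] <- 0L; f[ax(2, 0)] <- 2L; f[ax(1, 1)] <- 4L        # loop B
  f[ax(3, 0)] <- 3L; f[ax(4, 0)] <- 3L
  ls <- validate_loops(st, f)
  expect_length(ls$loops, 2L)
  expect_identical(as.integer(ls$status), c(1L, 1L))
  orc <- oracle_validate(st, f)
  expect_identical(as.integer(ls$status), as.integer(orc$status))
})

test_that("the crossing predicate agrees with dense spacetime sampling", {
  # far away: no crossing
  expect_false(crossing_test(c(10, 10), c(11, 10),
                             c(0, 0), c(1, 0), c(0.5, 0.866), c(1.5, 0.866)))
  # endpoint contact only: the point enters the site a mer vacates
  expect_false(crossing_test(c(-1, 0), c(0, 0),
                             c(0, 0), c(-0.5, 0.866), c(1, 0), c(1, 0)))
  # zero-length path
  expect_false(crossing_test(c(0.5, 0.1), c(0.5, 0.1),
                             c(0, 0), c(0, 0.05), c(1, 0), c(1, 0.05)))
  # constructed pass-through (fixture variant 4 geometry): solvent cuts
  # between two translating mers; analytic root s* = 1/2, projection 1/2
  expect_true(crossing_test(c(1, 0), c(0.5, 0.866),
                            c(0, 0), c(1, 0), c(0.5, 0.866), c(1.5, 0.866)))
  # randomized agreement with the sampling + root-refinement oracle
  set.seed(31)
  n_agree <- 0
  for (i in 1:300) {
    p0 <- runif(2, -1.5, 1.5); dp <- runif(2, -1, 1)
    b1 <- runif(2, -1.5, 1.5); d1 <- runif(2, -1, 1)
    b2 <- b1 + c(cos(a <- runif(1, 0, 2 * pi)), sin(a)); d2 <- runif(2, -1, 1)
    got <- crossing_test(p0, p0 + dp, b1, b1 + d1, b2, b2 + d2)
    want <- oracle_crossing(p0, dp, b1, d1, b2, d2)
    n_agree <- n_agree + (got == want)
  }
  expect_identical(n_agree, 300)
})

test_that("execute_step preserves every structural invariant", {
  # all-obstacle system: nothing moves, time still advances
  st <- system_from_layout(4, obstacle_sites = 1:16)
  r <- execute_step(st)
  expect_identical(r$tally$objects_moved, 0L)
  expect_identical(r$state$t, 1)
  # accepted 3-loop: exactly 3 objects move, hop vectors close a polygon
  fx <- make_fixtures()
  r <- execute_step(fx$variant5$state, fx$variant5$field)
  expect_identical(r$tally$objects_moved, 3L)
  expect_equal(sum(r$state$dispx), 0, tolerance = 1e-12)
  expect_equal(sum(r$state$dispy), 0, tolerance = 1e-12)
  expect_true(validate_state(r$state))
  # dimer bond survives the cooperative move (variant 5)
  lat <- build_lattice(4)
  s1 <- r$state$site_of[r$state$dimers[1, 1]]
  s2 <- r$state$site_of[r$state$dimers[1, 2]]
  expect_true(s2 %in% lat$nbr[s1, ])
  # determinism: identical state for identical seed
  st <- initialize_system(12, 0.1, 0.4, seed = 77)
  set.seed(13); a <- execute_step(st)$state
  set.seed(13); b <- execute_step(st)$state
  expect_identical(a$site_of, b$site_of)
  expect_identical(a$dispx, b$dispx)
})

test_that("trajectories sample on schedule and conserve the composition", {
  st <- initialize_system(12, 0.1, 0.4, seed = 9)
  expect_error(run_trajectory(st, 0), "invalid-argument")
  tr <- run_trajectory(st, 1)
  expect_identical(tr$times, c(0L, 1L))
  expect_error(run_trajectory(st, 5, schedule = c(0, 10)), "invalid-argument")
  # conservation at every sample: wrapped sites are always a permutation
  tr <- run_trajectory(st, 200)
  for (i in seq_along(tr$times))
    expect_identical(sort(tr$site[i, ]), seq_len(144L))
  expect_true(validate_state(tr$state))
  # pure solvent: same conservation, some motion every few steps
  st <- initialize_system(12, 0, 0, seed = 10)
  tr <- run_trajectory(st, 100)
  expect_gt(loop_statistics(tr)$mobile_fraction, 0)
})

test_that("the golden fixed-seed run regenerates bit-identically", {
  fx <- make_fixtures()
  a <- fx$golden$make()
  b <- fx$golden$make()
  expect_identical(a$posx, b$posx)
  expect_identical(a$site, b$site)
  expect_identical(a$tallies$decades, b$tallies$decades)
  # frozen summary pins the dynamics against silent drift
  expect_identical(max(a$times), 50L)
  expect_true(validate_state(a$state))
})
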