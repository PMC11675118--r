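# Property-style suites: conservation, bond rigidity, loop displacement
# closure, obstacle immobility, equality with the brute-force oracle, and
# box-size independence of the loop statistics.

test_that("species occupancy and bond rigidity are conserved over long runs", {
  for (cd in list(c(0, 0.5), c(0.12, 0.5), c(0.28, 0.70))) {
    st <- initialize_system(16, cd[1], cd[2],
                            seed = 1000 + round(100 * sum(cd)))
    comp0 <- st$composition
    obst0 <- which(st$species == species_codes()["obstacle"])
    tr <- run_trajectory(st, 1e4, points_per_decade = 5)
    fin <- tr$state
    # validator re-derives occupancy, counts and 100% dimer adjacency
    expect_true(validate_state(fin))
    expect_identical(fin$composition$n, comp0$n)
    # obstacle sites at t=0 are obstacle sites forever, with zero motion
    expect_identical(which(fin$species == species_codes()["obstacle"]), obst0)
    obj_obst <- fin$obj_species == species_codes()["obstacle"]
    expect_true(all(fin$dispx[obj_obst] == 0 & fin$dispy[obj_obst] == 0))
    # every dimer at exactly unit separation at every recorded sample
    lat <- build_lattice(16)
    for (i in seq_along(tr$times)) {
      ee2 <- tr$eex[i, ]^2 + tr$eey[i, ]^2
      expect_true(all(abs(ee2 - 1) < 1e-9))
    }
  }
})

test_that("accepted-loop hop vectors close modulo the box translations", {
  # the hop sum around a loop is exactly zero for contractible loops and a
  # lattice translation (multiple of L) for loops winding the torus
  offs <- cbind(c(1, 0, -1, -1, 0, 1), c(0, 1, 1, 0, -1, -1))
  set.seed(55)
  n_checked <- 0
  for (rep in 1:60) {
    L <- sample(6:10, 1)
    st <- initialize_system(L, sample(c(0, 0.1), 1), sample(c(0, 0.4), 1))
    f <- assign_vectors(st)
    ls <- validate_loops(st, f)
    for (j in seq_along(ls$loops)) {
      if (ls$status[j] != 0) next
      dirs <- f[ls$loops[[j]]] + 1L
      ax_sum <- colSums(offs[dirs, , drop = FALSE])
      expect_true(all(ax_sum %% L == 0))
      if (all(ax_sum == 0)) {
        uv <- cbind(offs[, 1] + offs[, 2] / 2, offs[, 2] * sqrt(3) / 2)
        expect_equal(colSums(uv[dirs, , drop = FALSE]), c(0, 0),
                     tolerance = 1e-9)
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 50)
})

test_that("center of mass is invariant under steps without winding loops", {
  offs <- cbind(c(1, 0, -1, -1, 0, 1), c(0, 1, 1, 0, -1, -1))
  set.seed(66)
  tested <- 0
  for (rep in 1:60) {
    st <- initialize_system(8, 0, 0.4)
    f <- assign_vectors(st)
    ls <- validate_loops(st, f)
    winding <- FALSE
    for (j in seq_along(ls$loops)) {
      if (ls$status[j] != 0) next
      if (any(colSums(offs[f[ls$loops[[j]]] + 1L, , drop = FALSE]) != 0))
        winding <- TRUE
    }
    if (winding) next
    r <- execute_step(st, f)
    mobile <- r$state$obj_species != species_codes()["obstacle"]
    expect_equal(sum(r$state$dispx[mobile]), 0, tolerance = 1e-9)
    expect_equal(sum(r$state$dispy[mobile]), 0, tolerance = 1e-9)
    tested <- tested + 1
  }
  expect_gt(tested, 20)
})

test_that("the engine's accepted loop set equals the brute-force oracle's", {
  set.seed(2024)
  comps <- expand.grid(c = c(0, 0.15, 0.3), d = c(0, 0.3, 0.6))
  n_fields <- 0
  for (L in c(4L, 5L, 6L)) {
    for (i in seq_len(nrow(comps))) {
      st <- initialize_system(L, comps$c[i], comps$d[i])
      for (k in 1:40) {
        f <- assign_vectors(st)
        eng <- validate_loops(st, f)
        orc <- oracle_validate(st, f)
        expect_identical(lapply(eng$loops, as.integer), orc$loops,
                         label = sprintf("loops L=%d c=%.2f d=%.2f rep %d",
                                         L, comps$c[i], comps$d[i], k))
        expect_identical(as.integer(eng$status), as.integer(orc$status),
                         label = sprintf("status L=%d c=%.2f d=%.2f rep %d",
                                         L, comps$c[i], comps$d[i], k))
        n_fields <- n_fields + 1
      }
    }
  }
  expect_gte(n_fields, 1000)
})

test_that("loop-length statistics do not depend on the box size", {
  set.seed(8)
  st64 <- initialize_system(64, 0, 0)
  tr64 <- run_trajectory(st64, 400, points_per_decade = 2)
  st128 <- initialize_system(128, 0, 0)
  tr128 <- run_trajectory(st128, 150, points_per_decade = 2)
  h64 <- loop_statistics(tr64)$length_distribution
  h128 <- loop_statistics(tr128)$length_distribution
  # common support, binned with a tail bin to keep expected counts healthy
  lens <- 3:9
  bin <- function(h) {
    cnt <- vapply(lens, function(l) sum(h$count_found[h$length == l]), 0)
    c(cnt, sum(h$count_found[h$length > max(lens)]))
  }
  tab <- rbind(bin(h64), bin(h128))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
  # mean loop length itself agrees closely
  expect_lt(abs(loop_statistics(tr64)$mean_length_found -
                  loop_statistics(tr128)$mean_length_found), 0.1)
})

test_that("the free liquid is Gaussian at long times", {
  set.seed(17)
  trajs <- lapply(1:3, function(i) {
    st <- initialize_system(32, 0, 0)
    run_trajectory(st, 2000)
  })
  a2 <- non_gaussian(trajs, "solvent")
  late <- a2$time >= max(a2$time) / 4
  expect_true(all(abs(a2$value[late]) < 0.1))
  # displacement components pass a normality check at the final time
  dx <- unlist(lapply(trajs, function(tr) {
    tr$posx[length(tr$times), ] - tr$posx[1, ]
  }))
  p <- stats::shapiro.test(sample(dx, min(length(dx), 3000)))$p.value
  expect_gt(p, 0.001)
})
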