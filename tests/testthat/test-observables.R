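# Observables layer, exercised mostly on constructed trajectories and on
# an ideal (constraint-free) lattice-walk surrogate with known moments.

test_that("msd handles degenerate and single-hop ensembles exactly", {
  times <- c(0L, 1L, 2L, 4L)
  # all objects stationary
  tr <- fake_trajectory(times, matrix(1, 4, 5), matrix(2, 4, 5))
  expect_true(all(msd(tr)$value == 0))
  # one of n objects hops one lattice unit at t=1 and stops
  px <- matrix(0, 4, 4); px[2:4, 1] <- 1
  tr <- fake_trajectory(times, px, matrix(0, 4, 4))
  expect_equal(msd(tr)$value, c(0, 0.25, 0.25, 0.25))
  expect_error(msd(tr, species = "nonsense"), "unknown species")
  expect_error(msd(list()), "empty")
})

test_that("msd of an ideal triangular-lattice walk is linear with unit slope", {
  tr <- ideal_walk_trajectory(800, 200, seed = 5)
  m <- msd(tr)
  fit <- lm(value ~ time + 0, data = as.data.frame(m[m$time > 0, ]))
  # each hop has length 1, so <dr^2> = t exactly in expectation
  expect_lt(abs(unname(coef(fit)[1]) - 1), 0.05)
  # single- and multi-origin estimates agree for this stationary process
  m2 <- msd(tr, origin_mode = "multi")
  common <- intersect(m$time[m$time > 0], m2$time)
  v1 <- m$value[match(common, m$time)]
  v2 <- m2$value[match(common, m2$time)]
  expect_lt(max(abs(v1 - v2) / pmax(v1, 1)), 0.15)
})

test_that("the non-Gaussian parameter matches closed-form moments", {
  set.seed(41)
  times <- c(0L, 1L)
  # isotropic 2D Gaussian: alpha2 = 0
  n <- 20000
  tr <- fake_trajectory(times, rbind(0, rnorm(n)), rbind(0, rnorm(n)))
  expect_lt(abs(non_gaussian(tr)$value[2]), 0.05)
  # all displacements of identical magnitude: alpha2 = -1/2 exactly
  th <- runif(500)
  tr <- fake_trajectory(times, rbind(0, cos(2 * pi * th)),
                        rbind(0, sin(2 * pi * th)))
  expect_equal(non_gaussian(tr)$value[2], -0.5, tolerance = 1e-12)
  # 50/50 mixture of 2D Gaussians with per-axis variances 1 and 9:
  # <r^2> = 10, <r^4> = 8(1 + 81)/2 = 328, alpha2 = 328/200 - 1 = 0.64,
  # and on any finite sample the estimator must equal the direct moments
  n <- 4000
  sd_mix <- rep(c(1, 3), each = n / 2)
  dx <- rnorm(n, sd = sd_mix); dy <- rnorm(n, sd = sd_mix)
  tr <- fake_trajectory(times, rbind(0, dx), rbind(0, dy))
  r2 <- dx^2 + dy^2
  expect_equal(non_gaussian(tr)$value[2], mean(r2^2) / (2 * mean(r2)^2) - 1,
               tolerance = 1e-12)
  expect_lt(abs(non_gaussian(tr)$value[2] - 0.64), 0.15)
  # alpha2(0) := 0 by convention
  expect_identical(non_gaussian(tr)$value[1], 0)
})

test_that("end-to-end autocorrelation reflects pure rotations exactly", {
  times <- c(0L, 1L, 2L)
  rot <- function(v, deg) {
    a <- deg * pi / 180
    c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
  }
  m <- 6
  e0 <- t(vapply(1:m, function(i) rot(c(1, 0), 60 * i), numeric(2)))
  e60 <- t(apply(e0, 1, rot, deg = 60))
  e180 <- -e0
  tr <- fake_trajectory(times, matrix(0, 3, 2 * m), matrix(0, 3, 2 * m),
                        eex = rbind(e0[, 1], e60[, 1], e180[, 1]),
                        eey = rbind(e0[, 2], e60[, 2], e180[, 2]),
                        obj_species = rep(1L, 2 * m),
                        dimers = cbind(seq(1, 2 * m, 2), seq(2, 2 * m, 2)))
  acf <- end_to_end_acf(tr)
  expect_equal(acf$value, c(1, 0.5, -1), tolerance = 1e-12)
  # no dimers: empty series, flagged
  tr0 <- fake_trajectory(times, matrix(0, 3, 2), matrix(0, 3, 2))
  expect_true(isTRUE(attr(end_to_end_acf(tr0), "empty")))
})

test_that("position autocorrelation uses wrapped site identity", {
  times <- 0:5
  # half the objects permanently displaced, half never move
  site <- matrix(1L, 6, 10)
  site[2:6, 1:5] <- 2L
  tr <- fake_trajectory(times, matrix(0, 6, 10), matrix(0, 6, 10), site = site)
  rho <- position_acf(tr)
  expect_equal(rho$value, c(1, rep(0.5, 5)))
  # 3-loop carousel: home at multiples of the period, away otherwise
  site <- matrix(0L, 7, 3)
  carousel <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  for (i in 0:6) site[i + 1, ] <- carousel[(i %% 3) + 1, ]
  tr <- fake_trajectory(0:6, matrix(0, 7, 3), matrix(0, 7, 3), site = site)
  rho <- position_acf(tr)
  expect_equal(rho$value, ifelse(0:6 %% 3 == 0, 1, 0))
})

test_that("trapped fraction agrees with a brute-force recount", {
  set.seed(3)
  times <- c(0L, 2L, 5L, 9L)
  n <- 40
  site <- matrix(sample.int(30, 4 * n, replace = TRUE), 4, n)
  site[, 1:12] <- matrix(site[1, 1:12], 4, 12, byrow = TRUE) # frozen objects
  tr <- fake_trajectory(times, matrix(0, 4, n), matrix(0, 4, n), site = site)
  tf <- trapped_fraction(tr, "solvent")
  # independent recount straight from the raw site matrix
  recount <- sum(vapply(seq_len(n),
                        function(i) all(site[, i] == site[1, i]), TRUE))
  expect_equal(tf$fraction, recount / n)
  expect_identical(tf$n_trapped + 0L, recount + 0L)
  # trapped fraction lower-bounds rho at every sampled time
  rho <- position_acf(tr)
  expect_true(all(rho$value >= tf$fraction - 1e-12))
  # excluding the trapped molecules lowers the curve
  expect_true(all(tf$rho_excluding$value[-1] <= rho$value[-1] + 1e-12))
  expect_error(trapped_fraction(tr, "solvent", window = c(100, 200)),
               "empty window")
})

test_that("loop statistics summarize tallies and flag immobile systems", {
  st <- system_from_layout(6, obstacle_sites = 1:36)
  tr <- run_trajectory(st, 50)
  ls <- loop_statistics(tr)
  expect_identical(nrow(ls$length_distribution), 0L)
  expect_identical(ls$mobile_fraction, 0)
  # a mobile liquid has loops of length >= 3 only, probabilities sum to 1
  st <- initialize_system(16, 0, 0, seed = 2)
  tr <- run_trajectory(st, 300)
  ls <- loop_statistics(tr)
  expect_true(all(ls$length_distribution$length >= 3))
  expect_equal(sum(ls$length_distribution$p_found), 1, tolerance = 1e-12)
  expect_gt(ls$mobile_fraction, 0)
})

test_that("observable series round-trip through the tidy CSV container", {
  st <- initialize_system(12, 0.1, 0.4, seed = 14)
  tr <- run_trajectory(st, 50)
  obs <- list(msd = msd(tr, "solvent"), rho = position_acf(tr, "solvent"))
  f <- tempfile(fileext = ".csv")
  write_observables(obs, f)
  back <- read_observables(f)
  orig <- do.call(rbind, lapply(obs, as.data.frame))
  expect_equal(back$value, orig$value, tolerance = 1e-12)
  expect_identical(back$statistic, orig$statistic)
})
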