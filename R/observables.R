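# Time-dependent observables over trajectory ensembles.  All MSD-type
# quantities use unwrapped coordinates; the position autocorrelation uses
# wrapped site identity (an object that wanders and returns counts as
# occupying its original position).

.as_ensemble <- function(trajectories) {
  if (inherits(trajectories, "dll_trajectory")) return(list(trajectories))
  if (!is.list(trajectories) || length(trajectories) == 0 ||
      !all(vapply(trajectories, inherits, logical(1), "dll_trajectory")))
    stop("empty or invalid trajectory ensemble")
  t0 <- trajectories[[1]]$times
  for (tr in trajectories)
    if (!identical(tr$times, t0))
      stop("all trajectories in an ensemble must share the sampling schedule")
  trajectories
}

# unwrapped x/y matrices for the requested species of one trajectory
.species_positions <- function(tr, species) {
  if (species == "solvent") {
    sel <- which(tr$obj_species == .SOLVENT)
    if (length(sel) == 0) stop("no solvent objects in trajectory")
    list(x = tr$posx[, sel, drop = FALSE], y = tr$posy[, sel, drop = FALSE])
  } else if (species == "mer") {
    sel <- which(tr$obj_species == .MER)
    if (length(sel) == 0) stop("no mers in trajectory")
    list(x = tr$posx[, sel, drop = FALSE], y = tr$posy[, sel, drop = FALSE])
  } else if (species == "dimer_com") {
    if (nrow(tr$dimers) == 0) stop("no dimers in trajectory")
    list(x = (tr$posx[, tr$dimers[, 1], drop = FALSE] +
                tr$posx[, tr$dimers[, 2], drop = FALSE]) / 2,
         y = (tr$posy[, tr$dimers[, 1], drop = FALSE] +
                tr$posy[, tr$dimers[, 2], drop = FALSE]) / 2)
  } else {
    stop("unknown species: ", species)
  }
}

.obs_series <- function(time, value, n, species, statistic) {
  structure(data.frame(time = time,
                       species = rep_len(species, length(time)),
                       statistic = rep_len(statistic, length(time)),
                       value = value,
                       n_ensemble = rep_len(n, length(time))),
            class = c("observable_series", "data.frame"))
}

# pooled displacement moments <dr^2>, <dr^4> per sample time
.disp_moments <- function(trajectories, species, origin_mode) {
  trajs <- .as_ensemble(trajectories)
  times <- trajs[[1]]$times
  if (origin_mode == "single") {
    s2 <- s4 <- numeric(length(times)); n <- 0
    for (tr in trajs) {
      p <- .species_positions(tr, species)
      dx <- sweep(p$x, 2, p$x[1, ])
      dy <- sweep(p$y, 2, p$y[1, ])
      r2 <- dx * dx + dy * dy
      s2 <- s2 + rowSums(r2)
      s4 <- s4 + rowSums(r2 * r2)
      n <- n + ncol(p$x)
    }
    list(time = times, m2 = s2 / n, m4 = s4 / n, n = n)
  } else if (origin_mode == "multi") {
    acc2 <- new.env(parent = emptyenv())
    S <- length(times)
    lag_s2 <- list(); lag_s4 <- list(); lag_n <- list()
    key <- function(l) sprintf("%d", l)
    for (tr in trajs) {
      p <- .species_positions(tr, species)
      for (i in seq_len(S - 1)) for (j in (i + 1):S) {
        l <- times[j] - times[i]
        dx <- p$x[j, ] - p$x[i, ]
        dy <- p$y[j, ] - p$y[i, ]
        r2 <- dx * dx + dy * dy
        k <- key(l)
        lag_s2[[k]] <- (if (is.null(lag_s2[[k]])) 0 else lag_s2[[k]]) + sum(r2)
        lag_s4[[k]] <- (if (is.null(lag_s4[[k]])) 0 else lag_s4[[k]]) + sum(r2 * r2)
        lag_n[[k]] <- (if (is.null(lag_n[[k]])) 0 else lag_n[[k]]) + length(r2)
      }
    }
    lags <- sort(as.numeric(names(lag_s2)))
    m2 <- vapply(lags, function(l) lag_s2[[key(l)]] / lag_n[[key(l)]], 0)
    m4 <- vapply(lags, function(l) lag_s4[[key(l)]] / lag_n[[key(l)]], 0)
    nn <- vapply(lags, function(l) lag_n[[key(l)]], 0)
    list(time = c(0, lags), m2 = c(0, m2), m4 = c(0, m4), n = max(nn))
  } else {
    stop("origin_mode must be 'single' or 'multi'")
  }
}

#' Mean square displacement
#'
#' `<dr^2(t)> = (1/n) sum_i |r_i(t) - r_i(0)|^2` averaged over objects and
#' trajectories, from unwrapped coordinates.  For `species = "dimer_com"`
#' the position is the center of mass of the two mers (which may sit at an
#' edge midpoint; it is treated in continuous Cartesian coordinates).
#'
#' @param trajectories A `dll_trajectory` or list of them sharing one
#'   sampling schedule.
#' @param species One of `"solvent"`, `"dimer_com"`, `"mer"`.
#' @param origin_mode `"single"` (default; displacement from t = 0,
#'   matching the many-independent-trajectories protocol) or `"multi"`
#'   (all sample-time pairs, for desk-scale variance reduction; flagged in
#'   the output statistic name).
#' @return An `observable_series` data frame with columns `time`,
#'   `species`, `statistic`, `value`, `n_ensemble`.
#' @export
msd <- function(trajectories, species = "solvent",
                origin_mode = c("single", "multi")) {
  origin_mode <- match.arg(origin_mode)
  mom <- .disp_moments(trajectories, species, origin_mode)
  stat <- if (origin_mode == "single") "msd" else "msd_multi_origin"
  .obs_series(mom$time, mom$m2, mom$n, species, stat)
}

#' Non-Gaussian parameter
#'
#' Two-dimensional non-Gaussian parameter
#' `alpha2(t) = <dr^4(t)> / (2 <dr^2(t)>^2) - 1`; zero for Gaussian
#' displacements, positive under dynamic heterogeneity.  `alpha2(0) = 0`
#' by convention (0/0 limit); later degenerate points (zero MSD with a
#' nonzero ensemble) return 0 and are flagged in the `degenerate`
#' attribute.
#'
#' @inheritParams msd
#' @return An `observable_series` with statistic `"alpha2"`.
#' @export
non_gaussian <- function(trajectories, species = "solvent",
                         origin_mode = c("single", "multi")) {
  origin_mode <- match.arg(origin_mode)
  mom <- .disp_moments(trajectories, species, origin_mode)
  a2 <- ifelse(mom$m2 > 0, mom$m4 / (2 * mom$m2^2) - 1, 0)
  a2[mom$time == 0] <- 0
  out <- .obs_series(mom$time, a2, mom$n, species, "alpha2")
  attr(out, "degenerate") <- mom$time > 0 & mom$m2 == 0
  out
}

#' End-to-end vector autocorrelation of dimers
#'
#' `<cos phi>(t) = (1/n) sum_i R_i(0) . R_i(t) / R_i^2(0)` over dimers and
#' trajectories; the end-to-end vector has unit length at all times, so
#' per-dimer values are cosines of multiples of 60 degrees.  The
#' orientation sign convention is fixed by the dimer table at t = 0.
#'
#' @inheritParams msd
#' @return An `observable_series` with statistic `"cos_phi"`, or an empty
#'   series flagged with attribute `empty = TRUE` when no dimers exist.
#' @export
end_to_end_acf <- function(trajectories) {
  trajs <- .as_ensemble(trajectories)
  times <- trajs[[1]]$times
  if (nrow(trajs[[1]]$dimers) == 0) {
    out <- .obs_series(numeric(0), numeric(0), 0L, "dimer", "cos_phi")
    attr(out, "empty") <- TRUE
    return(out)
  }
  s <- numeric(length(times)); n <- 0
  for (tr in trajs) {
    r0x <- tr$eex[1, ]; r0y <- tr$eey[1, ]
    cosphi <- sweep(tr$eex, 2, r0x, `*`) + sweep(tr$eey, 2, r0y, `*`)
    s <- s + rowSums(cosphi) # |R(0)|^2 = 1
    n <- n + ncol(tr$eex)
  }
  .obs_series(times, s / n, n, "dimer", "cos_phi")
}

.site_selection <- function(tr, species) {
  sel <- switch(species,
                solvent = which(tr$obj_species == .SOLVENT),
                mer = which(tr$obj_species == .MER),
                mobile = which(tr$obj_species != .OBSTACLE),
                stop("unknown species for site-based observable: ", species))
  if (length(sel) == 0) stop("no objects of species ", species)
  sel
}

#' Position autocorrelation function
#'
#' `rho(t) = (1/n) sum_i m_i(0) m_i(t)` with `m_i(t) = 1` iff object `i`
#' occupies its t = 0 lattice site at time `t` (wrapped site identity, so
#' an object that leaves and returns counts again; `rho` need not be
#' monotone).
#'
#' @inheritParams msd
#' @param species `"solvent"` (default), `"mer"`, or `"mobile"`.
#' @return An `observable_series` with statistic `"rho"`.
#' @export
position_acf <- function(trajectories, species = "solvent") {
  trajs <- .as_ensemble(trajectories)
  times <- trajs[[1]]$times
  s <- numeric(length(times)); n <- 0
  for (tr in trajs) {
    sel <- .site_selection(tr, species)
    at_home <- tr$site[, sel, drop = FALSE] ==
      matrix(tr$site[1, sel], nrow = length(times), ncol = length(sel),
             byrow = TRUE)
    s <- s + rowSums(at_home)
    n <- n + length(sel)
  }
  .obs_series(times, s / n, n, species, "rho")
}

#' Fraction of permanently trapped molecules
#'
#' Fraction of objects whose wrapped site never differs from their initial
#' site at any sample inside the window (molecules caged by obstacles for
#' the whole run).  Also returns `rho(t)` recomputed over the complement
#' (excluding the trapped molecules lowers the long-time plateau).
#'
#' @inheritParams position_acf
#' @param window Numeric `c(t_lo, t_hi)`; must contain at least one sampled
#'   time.
#' @return List with `fraction`, `n_trapped`, `n_total`, and
#'   `rho_excluding` (an `observable_series` over all sampled times).
#' @export
trapped_fraction <- function(trajectories, species = "solvent",
                             window = NULL) {
  trajs <- .as_ensemble(trajectories)
  times <- trajs[[1]]$times
  if (is.null(window)) window <- range(times)
  inw <- times >= window[1] & times <= window[2]
  if (!any(inw)) stop("empty window: no sampled times inside it")
  s_excl <- numeric(length(times)); n_excl <- 0L
  n_trap <- 0L; n_tot <- 0L
  for (tr in trajs) {
    sel <- .site_selection(tr, species)
    home <- matrix(tr$site[1, sel], nrow = length(times), ncol = length(sel),
                   byrow = TRUE)
    at_home <- tr$site[, sel, drop = FALSE] == home
    trapped <- colSums(!at_home[inw, , drop = FALSE]) == 0
    n_trap <- n_trap + sum(trapped)
    n_tot <- n_tot + length(sel)
    keep <- !trapped
    if (any(keep)) {
      s_excl <- s_excl + rowSums(at_home[, keep, drop = FALSE])
      n_excl <- n_excl + sum(keep)
    }
  }
  rho_excl <- if (n_excl > 0)
    .obs_series(times, s_excl / n_excl, n_excl, species, "rho_excluding_trapped")
  else
    .obs_series(times, rep(NA_real_, length(times)), 0L, species,
                "rho_excluding_trapped")
  list(fraction = n_trap / n_tot, n_trapped = n_trap, n_total = n_tot,
       rho_excluding = rho_excl)
}

#' Cooperative-loop statistics
#'
#' Summarizes the per-step loop tallies of one or more trajectories:
#' normalized loop-length distribution (found and accepted), mean loop
#' length, fraction of sites mobile per step, and rejection-reason rates.
#'
#' @param trajectories A `dll_trajectory` or list of them (schedules need
#'   not match; only tallies are used).
#' @return List with `length_distribution` (data frame: length,
#'   count_found, count_accepted, p_found, p_accepted), `mean_length_found`,
#'   `mean_length_accepted`, `mobile_fraction`, `rejection_rates`, and the
#'   pooled `totals`.
#' @export
loop_statistics <- function(trajectories) {
  if (inherits(trajectories, "dll_trajectory")) trajectories <- list(trajectories)
  hf <- 0; ha <- 0; dec <- 0
  n_sites <- trajectories[[1]]$L^2
  for (tr in trajectories) {
    hf <- hf + tr$tallies$length_hist_found
    ha <- ha + tr$tallies$length_hist_accepted
    dec <- dec + tr$tallies$decades
  }
  len <- seq_along(hf) - 1L
  keep <- hf > 0
  tot <- colSums(dec)
  steps <- tot[["steps"]]
  dist <- data.frame(length = len[keep], count_found = hf[keep],
                     count_accepted = ha[keep],
                     p_found = if (sum(hf) > 0) hf[keep] / sum(hf) else hf[keep],
                     p_accepted = if (sum(ha) > 0) ha[keep] / sum(ha) else ha[keep])
  found <- tot[["loops_found"]]
  list(length_distribution = dist,
       mean_length_found = if (sum(hf) > 0) sum(len * hf) / sum(hf) else NA_real_,
       mean_length_accepted = if (sum(ha) > 0) sum(len * ha) / sum(ha) else NA_real_,
       mobile_fraction = if (steps > 0) tot[["objects_moved"]] / (steps * n_sites) else 0,
       rejection_rates = c(
         bond_break = if (found > 0) tot[["rejected_bond_break"]] / found else 0,
         bond_cross = if (found > 0) tot[["rejected_bond_cross"]] / found else 0,
         two_cycle_share = if (found + tot[["two_cycles"]] > 0)
           tot[["two_cycles"]] / (found + tot[["two_cycles"]]) else 0),
       totals = tot)
}
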