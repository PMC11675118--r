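# Diffusion analysis: anomalous exponent from log-log MSD slopes, diffusion
# coefficients from the 2D Einstein relation <dr^2> = 4 D t, exponential
# obstacle-dependence of the short-time coefficient, and species ratios.

.window_points <- function(series, window) {
  stopifnot(inherits(series, "observable_series") || is.data.frame(series))
  sel <- series$time >= window[1] & series$time <= window[2] & series$time > 0
  series[sel, , drop = FALSE]
}

#' Fit the anomalous diffusion exponent
#'
#' Least-squares slope of `log MSD` vs `log t` over the window:
#' `MSD ~ t^alpha`, with walk dimension `d_w = 2/alpha`.  `alpha = 1` is
#' Fickian diffusion; `alpha < 1` subdiffusion.
#'
#' @param series An MSD `observable_series` (or data frame with `time` and
#'   `value`).
#' @param window Numeric `c(t_lo, t_hi)` in MC steps.
#' @return Object of class `diffusion_fit`: `alpha`, `d_w`, `r_squared`,
#'   `alpha_se`, `window`, `n_points`, `species`.
#' @export
fit_alpha <- function(series, window) {
  pts <- .window_points(series, window)
  if (nrow(pts) < 4) stop("insufficient points: need >= 4 in the fit window")
  if (any(pts$value <= 0)) stop("nonpositive MSD in the fit window")
  fit <- lm(log(value) ~ log(time), data = pts)
  alpha <- unname(coef(fit)[2])
  # noiseless synthetic input triggers a perfect-fit warning in summary()
  sm <- suppressWarnings(summary(fit))
  structure(list(alpha = alpha, d_w = 2 / alpha,
                 r_squared = sm$r.squared,
                 alpha_se = sm$coefficients[2, 2],
                 window = window, n_points = nrow(pts),
                 species = if ("species" %in% names(pts)) pts$species[1] else NA,
                 D = NA_real_, D_se = NA_real_, gated = NA),
            class = "diffusion_fit")
}

#' Fit a diffusion coefficient with an alpha gate
#'
#' `D` is the slope of `MSD` vs `t` over the window divided by 4 (Einstein
#' relation in two dimensions).  `D` is reported as gated-valid only when
#' [fit_alpha()] on the same window lies inside the gate; the default gate
#' is the symmetric `0.9 < alpha <= 1.1` (finite sampling can push alpha
#' slightly above 1), and `strict = TRUE` selects the one-sided
#' `0.9 < alpha < 1` gate.  A gate failure flags `D` as undefined rather
#' than raising an error.
#'
#' @inheritParams fit_alpha
#' @param gate Numeric `c(lo, hi)` for alpha (default `c(0.9, 1.1)`).
#' @param strict Use the one-sided gate `0.9 < alpha < 1`.
#' @return A `diffusion_fit` with `D`, `D_se`, `gated`, plus the alpha fit
#'   fields.
#' @export
fit_diffusion_coefficient <- function(series, window, gate = c(0.9, 1.1),
                                      strict = FALSE) {
  af <- fit_alpha(series, window)
  pts <- .window_points(series, window)
  lfit <- lm(value ~ time, data = pts)
  D <- unname(coef(lfit)[2]) / 4
  D_se <- suppressWarnings(summary(lfit))$coefficients[2, 2] / 4
  gated <- if (strict) af$alpha > 0.9 && af$alpha < 1
           else af$alpha > gate[1] && af$alpha <= gate[2]
  af$D <- if (gated) D else NA_real_
  af$D_ungated <- D
  af$D_se <- D_se
  af$gated <- gated
  af
}

#' Exponential decay of the diffusion coefficient with obstacle concentration
#'
#' Fits `D = D0 * exp(-a * c)` by least squares of `log D` on `c`.
#'
#' @param c_values Obstacle concentrations (>= 3 values).
#' @param D_values Positive diffusion coefficients, same length.
#' @return Object of class `decay_fit`: `D0`, `a`, `r_squared`,
#'   `residuals` (on the log scale).
#' @export
fit_exponential_decay <- function(c_values, D_values) {
  if (length(c_values) != length(D_values))
    stop("c_values and D_values must have equal length")
  if (length(c_values) < 3) stop("need >= 3 (c, D) pairs")
  if (any(D_values <= 0)) stop("nonpositive D")
  fit <- lm(log(D_values) ~ c_values)
  structure(list(D0 = exp(unname(coef(fit)[1])), a = -unname(coef(fit)[2]),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 residuals = unname(fit$residuals)),
            class = "decay_fit")
}

#' Ratio of two diffusion coefficients with propagated uncertainty
#'
#' `D_solvent / D_dimer` with a first-order (delta-method) standard error
#' from the two fit variances.  Both inputs must be gated-valid.
#'
#' @param fit_solvent,fit_dimer `diffusion_fit` objects from
#'   [fit_diffusion_coefficient()].
#' @return List with `ratio` and `se`.
#' @export
diffusion_ratio <- function(fit_solvent, fit_dimer) {
  if (!isTRUE(fit_solvent$gated) || !isTRUE(fit_dimer$gated))
    stop("undefined inputs: both fits must be gated-valid")
  r <- fit_solvent$D / fit_dimer$D
  se <- abs(r) * sqrt((fit_solvent$D_se / fit_solvent$D)^2 +
                        (fit_dimer$D_se / fit_dimer$D)^2)
  list(ratio = r, se = se)
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion_fit: alpha = %.4f (d_w = %.3f, R2 = %.4f), window [%g, %g]\n",
              x$alpha, x$d_w, x$r_squared, x$window[1], x$window[2]))
  if (!is.na(x$gated))
    cat(sprintf("  D = %s (gated %s)\n",
                ifelse(is.na(x$D), "undefined", sprintf("%.5g", x$D)),
                ifelse(x$gated, "valid", "failed")))
  invisible(x)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: D0 = %.5g, a = %.4f, R2 = %.4f\n",
              x$D0, x$a, x$r_squared))
  invisible(x)
}
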