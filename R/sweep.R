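# Affinity names that may be swept.
SWEEPABLE <- c("alpha", "beta", "gamma", "sigma", "delta_MY", "delta_YM",
               "theta", "xi", "phi", "kappa", "zeta", "mu_D", "mu_T", "rho")

#' Default parameter pairs swept for each model
#'
#' Model A: all pairs among the Factor A -> sox10, Sox10 -> mitfa and
#' Mitfa -| sox10 affinities. Model B: the Hdac gate on the Mitfa -> sox10
#' term (\code{xi}) against each affinity of the Mitfa--Sox10 module.
#' Model C: the Hdac gate on the Factor A term (\code{phi}) against each of
#' those plus \code{xi}.
#'
#' @param variant model variant.
#' @return list of length-2 character vectors.
#' @export
default_sweep_pairs <- function(variant) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  switch(variant,
    A = list(c("alpha", "gamma"), c("alpha", "beta"), c("gamma", "beta")),
    B = lapply(c("alpha", "beta", "delta_YM", "theta", "gamma"),
               function(p) c("xi", p)),
    C = lapply(c("alpha", "beta", "delta_YM", "theta", "gamma", "xi"),
               function(p) c("phi", p))
  )
}

#' Pairwise parameter-robustness sweep
#'
#' Varies two binding affinities on a log-spaced grid spanning
#' \code{fold_range} (default two orders of magnitude, centred on the base
#' value) and records, per grid point, the Mitfa and Sox10 steady-state
#' levels and the maximal Sox10 along a full wild-type re-integration.
#' Steady-state values are the end-of-run levels (the dynamics relax on a
#' ~5 hr scale, far shorter than the run). Integration failure at a grid
#' point is recorded as invalid, not fatal.
#'
#' @inheritParams grn_integrate
#' @param param_x,param_y names of the two affinities to vary (distinct).
#' @param fold_range total fold span of each axis (>= 1).
#' @param n_grid points per axis (>= 2, or 1 for the degenerate single-point
#'   grid).
#' @param base_params centre of the sweep.
#' @param theta_det,r_min thresholds used for the stored criteria mask (the
#'   mask is always re-derivable from the surfaces via
#'   \code{\link{acceptable_fraction}}).
#' @return object of class \code{grn_sweep}: axis values, surfaces
#'   \code{M_ss}, \code{S_ss}, \code{S_max} (matrices, x by y), validity and
#'   criteria masks.
#' @examples
#' sw <- sweep_pairwise("A", "alpha", "gamma", n_grid = 5, dt = 0.1)
#' acceptable_fraction(sw)
#' @export
sweep_pairwise <- function(variant, param_x, param_y, fold_range = 100,
                           n_grid = 21, base_params = grn_params(),
                           geno = genotype_wt(), t0 = 0, t1 = 96, dt = 0.05,
                           theta_det = 0.01, r_min = 5) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  param_x <- match.arg(param_x, SWEEPABLE)
  param_y <- match.arg(param_y, SWEEPABLE)
  if (param_x == param_y) stop("sweep_pairwise: param_x and param_y must differ")
  stopifnot(fold_range >= 1, n_grid >= 1)

  axis_vals <- function(base) {
    if (n_grid == 1) return(base)
    base * exp(seq(-log(fold_range) / 2, log(fold_range) / 2,
                   length.out = n_grid))
  }
  x_vals <- axis_vals(base_params[[param_x]])
  y_vals <- axis_vals(base_params[[param_y]])

  M_ss <- S_ss <- S_max <- matrix(NA_real_, n_grid, n_grid)
  valid <- matrix(FALSE, n_grid, n_grid)
  for (i in seq_len(n_grid)) {
    for (j in seq_len(n_grid)) {
      p <- base_params
      p[[param_x]] <- x_vals[i]
      p[[param_y]] <- y_vals[j]
      tr <- tryCatch(grn_integrate(variant, p, geno, t0 = t0, t1 = t1, dt = dt),
                     error = function(e) NULL)
      if (is.null(tr)) next
      n <- nrow(tr$values)
      M_ss[i, j] <- tr$values[n, "M"]
      S_ss[i, j] <- tr$values[n, "S"]
      S_max[i, j] <- max(tr$values[, "S"])
      valid[i, j] <- TRUE
    }
  }

  sw <- structure(list(variant = variant, genotype = geno,
                       param_x = param_x, param_y = param_y,
                       x_values = x_vals, y_values = y_vals,
                       fold_range = fold_range,
                       M_ss = M_ss, S_ss = S_ss, S_max = S_max,
                       valid = valid, theta_det = theta_det, r_min = r_min),
                  class = "grn_sweep")
  sw$mask <- criteria_mask(sw, theta_det, r_min)
  sw
}

# Boolean acceptability mask from the stored surfaces: high steady Mitfa, low
# steady Sox10, appreciable Sox10 peak. eps guards the peak-ratio division.
criteria_mask <- function(sw, theta_det, r_min, eps = 1e-6) {
  peak_ok <- (sw$S_max / pmax(sw$S_ss, eps) >= r_min) |
    (sw$S_ss < eps & sw$S_max >= theta_det)
  ok <- (sw$M_ss >= theta_det) & (sw$S_ss < theta_det) & peak_ok
  ok & sw$valid
}

#' Fraction of a sweep grid meeting the behaviour requirements
#'
#' Fraction of valid grid points where the three requirements hold
#' simultaneously: Mitfa steady state detectable (\code{M_ss >= theta_det}),
#' Sox10 steady state below detection (\code{S_ss < theta_det}), and an
#' appreciable Sox10 maximum (\code{S_max / S_ss >= r_min}; a vanishing
#' \code{S_ss} with a detectable \code{S_max} also satisfies the peak
#' requirement). This is the quantity that separates the accepted model
#' (non-zero over an extensive region) from the rejected ones (zero
#' everywhere on the default sweeps).
#'
#' @param sw a \code{\link{sweep_pairwise}} result.
#' @param theta_det detection threshold (nM).
#' @param r_min minimal peak-to-steady-state ratio.
#' @return fraction in \code{[0, 1]}.
#' @export
acceptable_fraction <- function(sw, theta_det = 0.01, r_min = 5) {
  stopifnot(inherits(sw, "grn_sweep"))
  if (!any(sw$valid)) stop("acceptable_fraction: all grid points invalid")
  mask <- criteria_mask(sw, theta_det, r_min)
  sum(mask) / sum(sw$valid)
}

#' @export
print.grn_sweep <- function(x, ...) {
  cat(sprintf("<grn_sweep> Model %s: %s x %s, %dx%d grid, %g-fold span\n",
              x$variant, x$param_x, x$param_y,
              length(x$x_values), length(x$y_values), x$fold_range))
  cat(sprintf("  valid points: %d/%d; acceptable fraction: %.3f\n",
              sum(x$valid), length(x$valid), acceptable_fraction(x)))
  invisible(x)
}

#' Long-format view of a sweep grid
#'
#' @param x a \code{grn_sweep}.
#' @param row.names,optional,... ignored (base generic signature).
#' @return data.frame with one row per grid point: the two parameter values,
#'   the three surfaces, validity and the acceptability mask.
#' @export
as.data.frame.grn_sweep <- function(x, row.names = NULL, optional = FALSE, ...) {
  n_x <- length(x$x_values); n_y <- length(x$y_values)
  df <- data.frame(
    param_x_value = rep(x$x_values, times = n_y),
    param_y_value = rep(x$y_values, each = n_x),
    M_ss = as.vector(x$M_ss), S_ss = as.vector(x$S_ss),
    S_max = as.vector(x$S_max),
    valid = as.vector(x$valid), ok = as.vector(x$mask),
    stringsAsFactors = FALSE
  )
  names(df)[1:2] <- c(paste0(x$param_x, "_value"), paste0(x$param_y, "_value"))
  df
}
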