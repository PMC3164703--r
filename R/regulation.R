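#' Hill-type activation fraction
#'
#' Fractional promoter occupancy by an activator under quasi-equilibrium
#' binding, \eqn{f(x; k) = kx / (1 + kx)}. The affinity \code{k} is the
#' binding/unbinding rate ratio, so \code{k*x} is dimensionless. First-order
#' (Hill coefficient 1) by construction; steeper responses in the models are
#' produced by explicit threshold gates (\code{\link{gate}}), not exponents.
#'
#' @param x concentration (nM), non-negative.
#' @param k affinity (1/nM), non-negative.
#' @return Activation fraction in \code{[0, 1)}; 0 at \code{x = 0},
#'   approaching 1 as \code{k*x} grows.
#' @seealso \code{\link{hill_rep}}, \code{\link{gate}}
#' @examples
#' hill_act(2, 3)  # 6/7
#' hill_act(1, 1)  # half-saturation
#' @export
hill_act <- function(x, k) {
  if (any(x < 0, na.rm = TRUE) || any(k < 0, na.rm = TRUE)) {
    stop("hill_act: concentrations and affinities must be non-negative")
  }
  kx <- k * x
  kx / (1 + kx)
}

#' Hill-type repression fraction
#'
#' Fraction of promoter activity surviving a repressor under quasi-equilibrium
#' binding, \eqn{g(x; k) = 1 / (1 + kx)}. Satisfies the occupancy identity
#' \code{hill_rep(x, k) == 1 - hill_act(x, k)}.
#'
#' @inheritParams hill_act
#' @return Repression survival fraction in \code{(0, 1]}; 1 with no repressor.
#' @export
hill_rep <- function(x, k) {
  if (any(x < 0, na.rm = TRUE) || any(k < 0, na.rm = TRUE)) {
    stop("hill_rep: concentrations and affinities must be non-negative")
  }
  1 / (1 + k * x)
}

#' Hard threshold gate
#'
#' Heaviside step used for the threshold response of the Factor Y feedback
#' loop: 1 if the input reaches the threshold (boundary inclusive), else 0.
#' The gate is what stabilises the mitfa-off state at low Mitfa or Factor Y.
#'
#' @param x concentration (nM), non-negative.
#' @param x_star threshold (nM), strictly positive.
#' @return 0 or 1 (vectorized over \code{x}).
#' @examples
#' gate(0.009, 0.01)  # 0
#' gate(0.01, 0.01)   # 1 (inclusive)
#' @export
gate <- function(x, x_star) {
  if (any(x < 0, na.rm = TRUE)) stop("gate: concentration must be non-negative")
  if (any(x_star <= 0)) stop("gate: threshold must be strictly positive")
  as.numeric(x >= x_star)
}

#' Smooth (steep-Hill) threshold gate
#'
#' Opt-in smooth alternative to \code{\link{gate}} for solver friendliness:
#' \eqn{x^n / (x^n + x_*^n)}. At the default steepness it matches the hard
#' gate away from the threshold and equals 1/2 exactly at it.
#'
#' @inheritParams gate
#' @param n Hill steepness of the soft gate (default 20).
#' @return value in \code{[0, 1)}.
#' @export
gate_soft <- function(x, x_star, n = 20) {
  if (any(x < 0, na.rm = TRUE)) stop("gate_soft: concentration must be non-negative")
  if (any(x_star <= 0)) stop("gate_soft: threshold must be strictly positive")
  r <- (x / x_star)^n
  r / (1 + r)
}
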