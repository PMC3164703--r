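# Scalar parameter names, in serialization order.
PARAM_SCALARS <- c(
  "c_S", "c_M", "c_H", "c_Y", "c_Z", "c_D", "c_T",
  "d_S", "d_M", "d_H", "d_Y", "d_Z", "d_D", "d_T",
  "alpha", "beta", "gamma", "sigma", "delta_MY", "delta_YM",
  "theta", "xi", "phi", "kappa", "zeta", "w_Z",
  "mu_D", "mu_T", "rho", "M_star", "Y_star"
)

#' Regulatory parameters of the melanocyte GRN models
#'
#' Constructs the full parameter set shared by Models A, B and C: per-species
#' maximal synthesis rates \code{c_g} (nM/hr) and first-order degradation
#' rates \code{d_g} (1/hr), binding-affinity ratios (1/nM) for every
#' regulatory arrow, the thresholds \code{M_star}/\code{Y_star} (nM) of the
#' Factor Y feedback gates, and the exogenous Factor A and Factor B pulses.
#'
#' The defaults are the package's calibrated reference set, frozen so that the
#' wild-type Model C run satisfies the three behaviour criteria (maintained
#' \emph{mitfa}; an interior \emph{sox10} peak well above its late level;
#' \emph{sox10} below the detection threshold at the end of the run) and the
#' mutant-panel contracts. Degradation rates of 0.2/hr set hours-scale
#' dynamics over 24--72 hpf; \code{c_g/d_g = 1} nM fixes the expression scale
#' for all gene products; Hdac activity is given a larger amplitude
#' (\code{c_H/d_H = 80} nM) because it is a recruited chromatin-modifying
#' activity, not a transcript, and its scale is free.
#'
#' @param ... named overrides of any parameter listed above, plus
#'   \code{pulse_A} and \code{pulse_B} (see \code{\link{pulse}}).
#' @return object of class \code{grn_params} (a validated named list).
#' @examples
#' p <- grn_params()
#' p2 <- grn_params(alpha = 2, phi = 20)
#' @export
grn_params <- function(...) {
  defaults <- list(
    # synthesis (nM/hr) and degradation (1/hr)
    c_S = 0.2, c_M = 0.2, c_H = 8.0, c_Y = 1.0, c_Z = 0.2, c_D = 0.2, c_T = 0.2,
    d_S = 0.2, d_M = 0.2, d_H = 0.1, d_Y = 0.2, d_Z = 0.2, d_D = 0.2, d_T = 0.2,
    # affinities (1/nM)
    alpha = 5,      # Factor A -> sox10 activation
    beta = 5,       # Mitfa -| sox10 repression
    gamma = 0.04,   # Sox10 -> mitfa activation (weak: mitfa idles low until the Factor Y loop ignites)
    sigma = 5,      # Mitfa -> sox10 activation (Hdac-gated term)
    delta_MY = 0.3, # Mitfa -> Factor Y activation
    delta_YM = 10,  # Factor Y -> mitfa activation
    theta = 0.6,    # Mitfa -> Hdac activation (weak response to idling Mitfa)
    xi = 10,        # Hdac -| (Mitfa -> sox10) repression
    phi = 10,       # Hdac -| (Factor A -> sox10) repression
    kappa = 5,      # Factor B -> Factor Z activation
    zeta = 5,       # Factor Z -> dct-class activation
    w_Z = 0.1,      # weak-activator weight on the Z -> D term
    mu_D = 5,       # Mitfa -> dct-class activation
    mu_T = 3,       # Mitfa -> tyrp1b activation
    rho = 5,        # Sox10 -| dct-class repression
    M_star = 0.01,  # Mitfa threshold for Factor Y induction (nM)
    Y_star = 0.01,  # Factor Y threshold for mitfa induction (nM)
    pulse_A = pulse(1, t_on = 12, t_off = Inf, decay_rate = 0),
    pulse_B = pulse(1, t_on = 12, t_off = 30, decay_rate = 0.2)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("grn_params: unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p <- defaults
  p[names(over)] <- over
  validate_params(p)
  structure(p, class = "grn_params")
}

validate_params <- function(p) {
  for (nm in PARAM_SCALARS) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop("grn_params: '", nm, "' must be a single non-negative number")
    }
  }
  if (p$w_Z > 1) stop("grn_params: w_Z must lie in (0, 1]")
  if (p$M_star <= 0 || p$Y_star <= 0) {
    stop("grn_params: thresholds M_star and Y_star must be strictly positive")
  }
  for (nm in c("pulse_A", "pulse_B")) {
    if (!inherits(p[[nm]], "grn_pulse")) stop("grn_params: '", nm, "' must be a pulse()")
  }
  invisible(p)
}

#' @export
print.grn_params <- function(x, ...) {
  cat("<grn_params> melanocyte GRN parameter set\n")
  sc <- unlist(x[PARAM_SCALARS])
  cat("  synthesis c_g (nM/hr):",
      paste(sprintf("%s=%g", sub("c_", "", names(sc)[1:7]), sc[1:7]), collapse = " "), "\n")
  cat("  degradation d_g (1/hr):",
      paste(sprintf("%s=%g", sub("d_", "", names(sc)[8:14]), sc[8:14]), collapse = " "), "\n")
  aff <- sc[15:length(sc)]
  cat("  affinities/thresholds:",
      paste(sprintf("%s=%g", names(aff), aff), collapse = " "), "\n")
  cat("  Factor A: "); print(x$pulse_A)
  cat("  Factor B: "); print(x$pulse_B)
  invisible(x)
}

#' Reduce a full parameter set to a model variant
#'
#' Models B and A are exact reductions of Model C: Model B removes the Hdac
#' gate on the Factor A input (\code{phi = 0}), the hard thresholds, and the
#' Factor B/Z route (\code{kappa = w_Z = c_Z = d_Z = 0}); Model A additionally
#' removes Hdac and Factor Y entirely (\code{sigma = xi = theta = delta_MY =
#' delta_YM = 0} and \code{c_H = d_H = c_Y = d_Y = 0}, so H' and Y' vanish
#' identically). With these settings the three right-hand sides nest exactly.
#'
#' @param params a \code{\link{grn_params}} object.
#' @param variant one of \code{"A"}, \code{"B"}, \code{"C"}.
#' @return list with elements \code{params} (reduced set) and
#'   \code{use_gates} (logical; thresholds are active only in Model C).
#' @export
variant_params <- function(params, variant) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  stopifnot(inherits(params, "grn_params"))
  p <- params
  use_gates <- variant == "C"
  if (variant %in% c("A", "B")) {
    p$phi <- 0
    p$kappa <- 0
    p$w_Z <- 0
    p$c_Z <- 0
    p$d_Z <- 0
  }
  if (variant == "A") {
    p$sigma <- 0; p$xi <- 0; p$theta <- 0
    p$delta_MY <- 0; p$delta_YM <- 0
    p$c_H <- 0; p$d_H <- 0
    p$c_Y <- 0; p$d_Y <- 0
  }
  list(params = p, use_gates = use_gates)
}
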