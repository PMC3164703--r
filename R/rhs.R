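# Builds the right-hand-side closure for one (variant, params, genotype)
# configuration. Single source of the model equations: the exported grn_rhs,
# the Euler integrator and the deSolve-based oracles all call the closure this
# returns. Parameters are bound as locals for speed.
make_rhs <- function(variant, params, genotype = genotype_wt(),
                     soft_gates = FALSE,
                     freeze_gates = NULL) {
  vp <- variant_params(params, variant)
  p <- vp$params
  use_gates <- vp$use_gates

  c_S <- p$c_S; c_M <- p$c_M; c_H <- p$c_H; c_Y <- p$c_Y
  c_Z <- p$c_Z; c_D <- p$c_D; c_T <- p$c_T
  d_S <- p$d_S; d_M <- p$d_M; d_H <- p$d_H; d_Y <- p$d_Y
  d_Z <- p$d_Z; d_D <- p$d_D; d_T <- p$d_T
  alpha <- p$alpha; beta <- p$beta; gamma_ <- p$gamma; sigma <- p$sigma
  delta_MY <- p$delta_MY; delta_YM <- p$delta_YM
  theta <- p$theta; xi <- p$xi; phi <- p$phi
  kappa <- p$kappa; zeta <- p$zeta; w_Z <- p$w_Z
  mu_D <- p$mu_D; mu_T <- p$mu_T; rho <- p$rho
  M_star <- p$M_star; Y_star <- p$Y_star
  pA <- p$pulse_A; pB <- p$pulse_B

  g_sox10 <- genotype$sox10_activity
  g_mitfa <- genotype$mitfa_activity
  g_Z <- genotype$factorZ_scale
  windows <- genotype$hdac_blocked_windows
  exo_M <- genotype$exogenous_M
  exo_S <- genotype$exogenous_S

  gate_fn <- if (soft_gates) function(x, xs) gate_soft(x, xs) else function(x, xs) as.numeric(x >= xs)
  frozen <- !is.null(freeze_gates)
  if (frozen) {
    thM_fix <- freeze_gates[["thM"]]
    thY_fix <- freeze_gates[["thY"]]
  }

  function(t, y) {
    if (any(is.na(y))) stop("rhs: NaN/NA in state")
    S <- y[[1]]; M <- y[[2]]; H <- y[[3]]; Y <- y[[4]]
    Z <- y[[5]]; D <- y[[6]]; T_ <- y[[7]]

    A_t <- pulse_value(t, pA)
    B_t <- pulse_value(t, pB)
    S_eff <- g_sox10 * S + pulse_value(t, exo_S)
    M_eff <- g_mitfa * M + pulse_value(t, exo_M)
    H_eff <- if (in_blocked_window(t, windows)) 0 else H

    if (!use_gates) {
      thM <- 1; thY <- 1
    } else if (frozen) {
      thM <- thM_fix; thY <- thY_fix
    } else {
      thM <- gate_fn(M_eff, M_star)
      thY <- gate_fn(Y, Y_star)
    }

    fA <- alpha * A_t / (1 + alpha * A_t)
    fMsig <- sigma * M_eff / (1 + sigma * M_eff)
    gHphi <- 1 / (1 + phi * H_eff)
    gHxi <- 1 / (1 + xi * H_eff)
    gMbeta <- 1 / (1 + beta * M_eff)
    fSgam <- gamma_ * S_eff / (1 + gamma_ * S_eff)
    fYdel <- delta_YM * Y / (1 + delta_YM * Y)
    fMthe <- theta * M_eff / (1 + theta * M_eff)
    fMdel <- delta_MY * M_eff / (1 + delta_MY * M_eff)
    fB <- kappa * B_t / (1 + kappa * B_t)
    fMmuD <- mu_D * M_eff / (1 + mu_D * M_eff)
    fZ <- zeta * Z / (1 + zeta * Z)
    gSrho <- 1 / (1 + rho * S_eff)
    fMmuT <- mu_T * M_eff / (1 + mu_T * M_eff)

    dS <- c_S * min(1, fA * gHphi + fMsig * gHxi) * gMbeta - d_S * S
    dM <- c_M * min(1, fSgam + fYdel * thY) - d_M * M
    dH <- c_H * fMthe - d_H * H
    dY <- c_Y * fMdel * thM - d_Y * Y
    dZ <- c_Z * g_Z * fB - d_Z * Z
    dD <- c_D * min(1, fMmuD + w_Z * fZ) * gSrho - d_D * D
    dT <- c_T * fMmuT - d_T * T_

    c(dS, dM, dH, dY, dZ, dD, dT)
  }
}

#' Right-hand side of the melanocyte GRN ODE system
#'
#' Time derivatives (nM/hr) of the seven state species \code{S} (sox10
#' product), \code{M} (mitfa product), \code{H} (Hdac activity), \code{Y}
#' (Factor Y), \code{Z} (Factor Z), \code{D} (dct-class differentiation gene
#' product) and \code{T} (tyrp1b product) under exogenous inputs Factor A and
#' Factor B. Multiple activators on one promoter combine additively and are
#' capped at 1 (promoter saturation), so \code{c_g} remains the true maximal
#' rate; Hdac repression multiplies each sox10 activation term it gates; the
#' Factor Y loop carries hard threshold gates in Model C only.
#'
#' @param variant model variant, \code{"A"}, \code{"B"} or \code{"C"}.
#' @param state named (or ordered \code{S,M,H,Y,Z,D,T}) non-negative numeric
#'   vector of length 7, nM.
#' @param t time (hpf).
#' @param params a \code{\link{grn_params}} object.
#' @param geno a \code{\link{genotype}}.
#' @param soft_gates if \code{TRUE} use the smooth \code{\link{gate_soft}}
#'   in place of the hard Heaviside gates (Model C only).
#' @return named derivative vector (nM/hr) over the seven state species.
#' @examples
#' grn_rhs("A", rep(0, 7), t = 0, params = grn_params())
#' @export
grn_rhs <- function(variant, state, t, params, geno = genotype_wt(),
                    soft_gates = FALSE) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  state <- as_state(state)
  if (any(is.na(state))) stop("grn_rhs: NaN/NA in state")
  if (any(state < 0)) stop("grn_rhs: state must be non-negative")
  f <- make_rhs(variant, params, geno, soft_gates = soft_gates)
  d <- f(t, state)
  names(d) <- SPECIES
  d
}

# Coerce a user-supplied state to the canonical 7-vector in SPECIES order.
as_state <- function(state) {
  if (length(state) != length(SPECIES)) {
    stop("state must have length ", length(SPECIES), " (species ",
         paste(SPECIES, collapse = ","), ")")
  }
  if (!is.null(names(state)) && all(names(state) != "")) {
    if (!setequal(names(state), SPECIES)) {
      stop("state names must be exactly: ", paste(SPECIES, collapse = ","))
    }
    state <- state[SPECIES]
  }
  as.numeric(state)
}
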