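# Time at which pulses are considered fully relaxed ("constant-input
# regime"): decaying pulses have vanished, constant ones hold their plateau.
.T_LATE_INPUT <- 1e6

# Per-species steady value from balance synth = d * x; NA when degenerate
# (no degradation but nonzero synthesis).
ss_balance <- function(synth, d) {
  if (d > 0) return(synth / d)
  if (synth == 0) return(0)
  NA_real_
}

#' Find all fixed points of a model in the constant-input regime
#'
#' Steady states are obtained by setting the time derivatives to zero with
#' the exogenous inputs at their late-time values and solving the resulting
#' algebraic system. Given the inputs the system is triangular apart from the
#' sox10--mitfa pair, so each candidate reduces to a scalar fixed-point
#' equation in Mitfa; the hard threshold gates of Model C are handled by
#' enumerating the (at most four) gate regimes, solving each smooth system,
#' and keeping only regime-self-consistent roots. Every returned point is
#' verified against the full right-hand side and classified for stability
#' from the eigenvalues of the frozen-gate Jacobian.
#'
#' @inheritParams grn_rhs
#' @param n_starts number of log-spaced scan points per gate regime used to
#'   bracket roots of the scalar Mitfa equation (default 200).
#' @param tol residual tolerance, max |rhs| at the fixed point (nM/hr).
#' @return list of \code{grn_steady_state} objects, each with
#'   \code{concentrations} (named, nM), \code{stable} (logical, \code{NA} if
#'   boundary-degenerate), \code{regime} (gate outcomes), \code{residual}.
#' @examples
#' ss <- find_steady_states("C", grn_params(), genotype_sox10_null())
#' sapply(ss, function(s) s$concentrations["M"])
#' @export
find_steady_states <- function(variant, params, geno = genotype_wt(),
                               n_starts = 200, tol = 1e-10) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  stopifnot(inherits(params, "grn_params"), n_starts >= 1)
  vp <- variant_params(params, variant)
  p <- vp$params
  use_gates <- vp$use_gates
  t_eval <- .T_LATE_INPUT

  if (p$d_M <= 0 && p$c_M > 0) {
    stop("find_steady_states: d_M must be positive when c_M > 0")
  }

  A_inf <- pulse_value(t_eval, p$pulse_A)
  B_inf <- pulse_value(t_eval, p$pulse_B)
  exoM <- pulse_value(t_eval, geno$exogenous_M)
  exoS <- pulse_value(t_eval, geno$exogenous_S)
  gS <- geno$sox10_activity; gM <- geno$mitfa_activity

  fA <- hill_act(A_inf, p$alpha)
  Z_ss <- ss_balance(p$c_Z * geno$factorZ_scale * hill_act(B_inf, p$kappa), p$d_Z)

  # Candidate full state as a function of M in a given gate regime.
  state_of_M <- function(M, thM) {
    M_eff <- gM * M + exoM
    H <- ss_balance(p$c_H * hill_act(M_eff, p$theta), p$d_H)
    if (is.na(H)) return(NULL)
    S <- ss_balance(
      p$c_S * min(1, fA * hill_rep(H, p$phi) +
                    hill_act(M_eff, p$sigma) * hill_rep(H, p$xi)) *
        hill_rep(M_eff, p$beta), p$d_S)
    Y <- ss_balance(p$c_Y * hill_act(M_eff, p$delta_MY) * thM, p$d_Y)
    if (is.na(S) || is.na(Y) || is.na(Z_ss)) return(NULL)
    S_eff <- gS * S + exoS
    D <- ss_balance(
      p$c_D * min(1, hill_act(M_eff, p$mu_D) + p$w_Z * hill_act(Z_ss, p$zeta)) *
        hill_rep(S_eff, p$rho), p$d_D)
    T_ <- ss_balance(p$c_T * hill_act(M_eff, p$mu_T), p$d_T)
    if (is.na(D) || is.na(T_)) return(NULL)
    st <- c(S, M, H, Y, Z_ss, D, T_)
    names(st) <- SPECIES
    st
  }

  # Scalar mitfa fixed-point equation within a regime.
  G_of_M <- function(M, thM, thY) {
    st <- state_of_M(M, thM)
    if (is.null(st)) return(NA_real_)
    S_eff <- gS * st[["S"]] + exoS
    target <- ss_balance(
      p$c_M * min(1, hill_act(S_eff, p$gamma) +
                    hill_act(st[["Y"]], p$delta_YM) * thY), p$d_M)
    if (is.na(target)) return(NA_real_)
    target - M
  }

  regimes <- if (use_gates) {
    list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  } else {
    list(c(1, 1))
  }

  M_max <- if (p$d_M > 0) p$c_M / p$d_M else 0
  M_hi <- M_max * 1.0 + 1e-12
  grid <- unique(c(0, exp(seq(log(max(M_hi * 1e-8, 1e-12)), log(max(M_hi, 1e-12)),
                              length.out = max(n_starts, 2)))))

  found <- list()
  diagnostics <- character(0)
  for (rg in regimes) {
    thM <- rg[1]; thY <- rg[2]
    Gv <- vapply(grid, G_of_M, numeric(1), thM = thM, thY = thY)
    ok <- !is.na(Gv)
    if (!any(ok)) next
    g_ok <- grid[ok]; Gv_ok <- Gv[ok]
    diagnostics <- c(diagnostics,
                     sprintf("regime (thM=%d, thY=%d): min |G| = %.3g", thM, thY,
                             min(abs(Gv_ok))))
    roots <- numeric(0)
    exact0 <- which(Gv_ok == 0)
    roots <- c(roots, g_ok[exact0])
    if (length(g_ok) > 1) {
      sgn <- sign(Gv_ok)
      cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
      for (i in cross) {
        r <- tryCatch(uniroot(function(m) G_of_M(m, thM, thY),
                              lower = g_ok[i], upper = g_ok[i + 1],
                              tol = 1e-13)$root,
                      error = function(e) NA_real_)
        if (!is.na(r)) roots <- c(roots, r)
      }
    }
    for (M in roots) {
      st <- state_of_M(M, thM)
      if (is.null(st)) next
      # regime self-consistency (inclusive gate boundary)
      if (use_gates) {
        M_eff <- gM * M + exoM
        if (as.numeric(M_eff >= p$M_star) != thM) next
        if (as.numeric(st[["Y"]] >= p$Y_star) != thY) next
      }
      rhs_full <- make_rhs(variant, params, geno)
      res <- max(abs(rhs_full(t_eval, st)))
      if (res > tol) next
      found[[length(found) + 1]] <- list(state = st, regime = c(thM = thM, thY = thY),
                                         residual = res)
    }
  }

  if (length(found) == 0) {
    stop("find_steady_states: no self-consistent fixed point found; ",
         "residual landscape: ", paste(diagnostics, collapse = "; "))
  }

  # deduplicate within tolerance across regimes
  dedup <- list()
  for (f in found) {
    dup <- any(vapply(dedup, function(g) max(abs(g$state - f$state)) < 1e-6, logical(1)))
    if (!dup) dedup[[length(dedup) + 1]] <- f
  }

  lapply(dedup, function(f) {
    ss <- structure(list(variant = variant, genotype = geno,
                         concentrations = f$state, regime = f$regime,
                         residual = f$residual, stable = NA),
                    class = "grn_steady_state")
    ss$stable <- classify_stability(ss, params)
    ss
  })
}

#' Stability of a fixed point from the frozen-gate Jacobian
#'
#' Computes a central finite-difference Jacobian of the right-hand side at
#' the fixed point with the threshold gates frozen at the point's regime, and
#' reports stability as all eigenvalues having negative real part. A point
#' within \code{eps} of a gate boundary is boundary-degenerate and returns
#' \code{NA}.
#'
#' @param ss a \code{grn_steady_state} from \code{\link{find_steady_states}}.
#' @param params the \code{\link{grn_params}} used to find it.
#' @param eps gate-boundary guard distance (nM).
#' @return \code{TRUE}, \code{FALSE}, or \code{NA} (boundary-degenerate).
#' @export
classify_stability <- function(ss, params, eps = 1e-6) {
  stopifnot(inherits(ss, "grn_steady_state"))
  vp <- variant_params(params, ss$variant)
  p <- vp$params
  geno <- ss$genotype
  x <- ss$concentrations
  t_eval <- .T_LATE_INPUT
  if (vp$use_gates) {
    M_eff <- geno$mitfa_activity * x[["M"]] + pulse_value(t_eval, geno$exogenous_M)
    if (abs(M_eff - p$M_star) < eps || abs(x[["Y"]] - p$Y_star) < eps) {
      return(NA)
    }
  }
  f <- make_rhs(ss$variant, params, geno,
                freeze_gates = list(thM = unname(ss$regime["thM"]),
                                    thY = unname(ss$regime["thY"])))
  J <- jacobian_fd(function(y) f(t_eval, y), as.numeric(x))
  # species frozen out of the variant (c_g = d_g = 0) contribute identically
  # zero rows; stability is decided on the active subsystem (the full matrix
  # is block-triangular, so this is exact)
  cg <- unlist(p[paste0("c_", SPECIES)], use.names = FALSE)
  dg <- unlist(p[paste0("d_", SPECIES)], use.names = FALSE)
  active <- !(cg == 0 & dg == 0)
  ev <- eigen(J[active, active, drop = FALSE], only.values = TRUE)$values
  all(Re(ev) < 0)
}

jacobian_fd <- function(fn, x, h_rel = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- h_rel * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- max(x[j] - h, 0)
    J[, j] <- (fn(xp) - fn(xm)) / (xp[j] - xm[j])
  }
  J
}

#' Cross-validate a stable fixed point against the integrator
#'
#' Integrates from the fixed point perturbed by plus/minus 1% and checks that
#' both perturbed trajectories return to within \code{tol2} of the fixed
#' point by \code{horizon} hours, guaranteeing solver/integrator agreement.
#'
#' @inheritParams classify_stability
#' @param horizon integration horizon (hr).
#' @param tol2 maximal allowed end-point distance (nM).
#' @param dt Euler step used for the check (hr).
#' @return \code{TRUE} if both perturbations re-converge, else \code{FALSE}.
#' @export
consistency_check <- function(ss, params, horizon = 150, tol2 = 1e-4, dt = 0.02) {
  stopifnot(inherits(ss, "grn_steady_state"))
  x <- as.numeric(ss$concentrations)
  t0 <- .T_LATE_INPUT
  for (fac in c(1.01, 0.99)) {
    tr <- grn_integrate(ss$variant, params, ss$genotype,
                        t0 = t0, t1 = t0 + horizon, dt = dt, init = fac * x)
    endpt <- tr$values[nrow(tr$values), ]
    if (max(abs(endpt - x)) > tol2) return(FALSE)
  }
  TRUE
}

#' @export
print.grn_steady_state <- function(x, ...) {
  cat(sprintf("<grn_steady_state> Model %s, %s | %s | residual %.2g\n",
              x$variant, genotype_label(x$genotype),
              if (isTRUE(x$stable)) "stable" else if (isFALSE(x$stable)) "unstable"
              else "boundary-degenerate", x$residual))
  cat("  ", paste(sprintf("%s=%.4g", SPECIES, x$concentrations), collapse = " "), "\n")
  cat(sprintf("  gate regime: thM=%d thY=%d\n", x$regime["thM"], x$regime["thY"]))
  invisible(x)
}
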