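#' Genotype and treatment description
#'
#' Represents a mutant/morphant/drug scenario as activity masking: state
#' variables keep evolving (transcripts are still produced in mutants, as
#' observed for \emph{sox10} and \emph{mitfa}), but the downstream
#' \emph{regulatory influence} of a product is scaled by its activity, and
#' Hdac contributes no repression during blocked (inhibitor) windows.
#'
#' @param sox10_activity scalar in \code{[0, 1]}; 0 models a \emph{sox10} null.
#' @param mitfa_activity scalar in \code{[0, 1]}; 0 models a \emph{mitfa} null.
#' @param factorZ_scale scalar in \code{[0, 1]} scaling Factor Z production
#'   (models Sox9b morpholino knockdown).
#' @param hdac_blocked_windows list of \code{c(t_start, t_end)} hpf intervals
#'   (non-overlapping, ordered) during which Hdac exerts no repression
#'   (Trichostatin-A-style inhibition).
#' @param exogenous_M,exogenous_S optional \code{\link{pulse}} objects adding
#'   functional Mitfa/Sox10 activity (rescue or RNA injection).
#' @return object of class \code{grn_genotype}.
#' @examples
#' genotype_wt()
#' genotype(sox10_activity = 0, exogenous_M = pulse(0.1, 30, 40, 1))
#' @export
genotype <- function(sox10_activity = 1, mitfa_activity = 1, factorZ_scale = 1,
                     hdac_blocked_windows = list(),
                     exogenous_M = NULL, exogenous_S = NULL) {
  chk01 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("genotype: '", nm, "' must be a scalar in [0, 1]")
    }
  }
  chk01(sox10_activity, "sox10_activity")
  chk01(mitfa_activity, "mitfa_activity")
  chk01(factorZ_scale, "factorZ_scale")
  if (!is.list(hdac_blocked_windows)) stop("genotype: hdac_blocked_windows must be a list")
  if (length(hdac_blocked_windows) > 0) {
    w <- do.call(rbind, lapply(hdac_blocked_windows, function(x) {
      if (length(x) != 2 || !is.numeric(x)) {
        stop("genotype: each blocked window must be numeric c(t_start, t_end)")
      }
      if (x[1] > x[2]) stop("genotype: blocked window start must not exceed end")
      as.numeric(x)
    }))
    if (nrow(w) > 1) {
      if (any(diff(w[, 1]) <= 0) || any(w[-1, 1] < w[-nrow(w), 2])) {
        stop("genotype: blocked windows must be ordered and non-overlapping")
      }
    }
  }
  for (nm in c("exogenous_M", "exogenous_S")) {
    v <- get(nm)
    if (!is.null(v) && !inherits(v, "grn_pulse")) {
      stop("genotype: '", nm, "' must be NULL or a pulse()")
    }
  }
  structure(list(sox10_activity = sox10_activity,
                 mitfa_activity = mitfa_activity,
                 factorZ_scale = factorZ_scale,
                 hdac_blocked_windows = hdac_blocked_windows,
                 exogenous_M = exogenous_M, exogenous_S = exogenous_S),
            class = "grn_genotype")
}

#' @rdname genotype
#' @export
genotype_wt <- function() genotype()

#' @rdname genotype
#' @export
genotype_mitfa_null <- function() genotype(mitfa_activity = 0)

#' @rdname genotype
#' @export
genotype_sox10_null <- function() genotype(sox10_activity = 0)

#' @rdname genotype
#' @export
genotype_double_null <- function() genotype(sox10_activity = 0, mitfa_activity = 0)

#' @export
print.grn_genotype <- function(x, ...) {
  cat(sprintf("<grn_genotype> sox10 %.2f | mitfa %.2f | FactorZ %.2f\n",
              x$sox10_activity, x$mitfa_activity, x$factorZ_scale))
  if (length(x$hdac_blocked_windows) > 0) {
    cat("  Hdac blocked:",
        paste(vapply(x$hdac_blocked_windows,
                     function(w) sprintf("[%g, %g]", w[1], w[2]), ""),
              collapse = " "), "hpf\n")
  }
  if (!is.null(x$exogenous_M)) { cat("  exogenous Mitfa: "); print(x$exogenous_M) }
  if (!is.null(x$exogenous_S)) { cat("  exogenous Sox10: "); print(x$exogenous_S) }
  invisible(x)
}

in_blocked_window <- function(t, windows) {
  for (w in windows) if (t >= w[1] && t <= w[2]) return(TRUE)
  FALSE
}

#' Effective regulatory activities under a genotype
#'
#' Maps raw state concentrations to the activities actually seen by target
#' promoters: mutant products are scaled by their activity (the transcript
#' keeps evolving, only its influence is masked), exogenous rescue pulses add
#' functional protein, and Hdac contributes zero repression inside blocked
#' windows.
#'
#' @param state named numeric state vector (at least \code{S}, \code{M},
#'   \code{H}), concentrations in nM.
#' @param geno a \code{\link{genotype}}.
#' @param t time (hpf) at which exogenous pulses and windows are evaluated.
#' @return named numeric vector \code{c(S_eff, M_eff, H_eff)}.
#' @export
effective_activities <- function(state, geno, t = 0) {
  stopifnot(inherits(geno, "grn_genotype"))
  if (any(state < 0, na.rm = TRUE)) stop("effective_activities: state must be non-negative")
  S_eff <- geno$sox10_activity * state[["S"]] + pulse_value(t, geno$exogenous_S)
  M_eff <- geno$mitfa_activity * state[["M"]] + pulse_value(t, geno$exogenous_M)
  H_eff <- if (in_blocked_window(t, geno$hdac_blocked_windows)) 0 else state[["H"]]
  c(S_eff = S_eff, M_eff = M_eff, H_eff = H_eff)
}
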