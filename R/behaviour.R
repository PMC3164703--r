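#' Behaviour-criteria classification of a trajectory
#'
#' Quantifies the three qualitative criteria a credible wild-type melanocyte
#' simulation must satisfy: (i) long-term maintenance of \emph{mitfa}
#' expression, (ii) an initial rise of \emph{sox10} to an interior maximum,
#' and (iii) long-term loss of \emph{sox10} (below a detection threshold).
#'
#' @param traj a \code{\link{grn_integrate}} trajectory.
#' @param theta_det detection threshold (nM); the level above which a
#'   transcript counts as detectable by in situ hybridisation. Default 0.01,
#'   the same scale as the Factor Y loop thresholds. A declared convention,
#'   not a measured value.
#' @param t_late time (hpf) after which \emph{mitfa} must stay detectable;
#'   default 60, past the stage at which melanocytes have lost sox10 signal.
#' @param r_min minimal ratio of the \emph{sox10} maximum to its final level
#'   for the peak to count as "appreciable"; default 5.
#' @return object of class \code{grn_behaviour}: list with logical
#'   \code{mitfa_maintained}, \code{sox10_transient_peak},
#'   \code{sox10_off_late}, and numeric \code{peak_ratio}, \code{t_peak}.
#' @examples
#' fl <- behaviour_flags(grn_integrate("C", grn_params(), dt = 0.05))
#' fl$peak_ratio
#' @export
behaviour_flags <- function(traj, theta_det = 0.01, t_late = 60, r_min = 5) {
  stopifnot(inherits(traj, "grn_trajectory"))
  if (length(traj$times) == 0) stop("behaviour_flags: empty trajectory")
  if (t_late < traj$times[1] || t_late > traj$times[length(traj$times)]) {
    stop("behaviour_flags: t_late outside trajectory range")
  }
  eps <- 1e-9
  S <- trajectory_species(traj, "S")
  M <- trajectory_species(traj, "M")
  n <- length(S)

  mitfa_maintained <- all(M[traj$times >= t_late] >= theta_det)
  S_end <- S[n]
  sox10_off_late <- S_end < theta_det
  i_peak <- which.max(S)
  peak_ratio <- max(S) / max(S_end, eps)
  t_peak <- traj$times[i_peak]
  interior <- i_peak > 1 && i_peak < n
  sox10_transient_peak <- interior && peak_ratio >= r_min

  structure(list(mitfa_maintained = mitfa_maintained,
                 sox10_transient_peak = sox10_transient_peak,
                 sox10_off_late = sox10_off_late,
                 peak_ratio = peak_ratio, t_peak = t_peak),
            class = "grn_behaviour")
}

#' @export
print.grn_behaviour <- function(x, ...) {
  cat("<grn_behaviour>\n")
  cat(sprintf("  mitfa maintained:      %s\n", x$mitfa_maintained))
  cat(sprintf("  sox10 transient peak:  %s (ratio %.3g at %.1f hpf)\n",
              x$sox10_transient_peak, x$peak_ratio, x$t_peak))
  cat(sprintf("  sox10 off at end:      %s\n", x$sox10_off_late))
  invisible(x)
}
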