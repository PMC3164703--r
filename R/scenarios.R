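#' Time spent above a detection threshold
#'
#' Total time (hr) a species' concentration is at or above \code{theta}
#' (counted as \code{dt} per grid point at or above threshold).
#'
#' @inheritParams trajectory_species
#' @param theta threshold (nM).
#' @return duration in hours.
#' @export
duration_above <- function(traj, species, theta) {
  x <- trajectory_species(traj, species)
  sum(x >= theta) * traj$dt
}

#' Peak level of a species along a trajectory
#'
#' @inheritParams trajectory_species
#' @return maximal concentration (nM).
#' @export
peak_level <- function(traj, species) {
  max(trajectory_species(traj, species))
}

#' Area under a species' concentration curve
#'
#' Trapezoidal time integral (nM * hr), used as the melanisation proxy for
#' the dct-class readout.
#'
#' @inheritParams trajectory_species
#' @return AUC in nM * hr.
#' @export
auc_species <- function(traj, species) {
  x <- trajectory_species(traj, species)
  tt <- traj$times
  sum(diff(tt) * (x[-1] + x[-length(x)]) / 2)
}

#' Simulate the four-genotype panel for one model
#'
#' Runs wild type, \emph{mitfa} null, \emph{sox10} null and the double
#' mutant on a shared grid and evaluates the qualitative contracts the
#' experimental data impose on Model C: the dct-class readout is transiently
#' detectable in all three mutants, weakest and most transient in the
#' \emph{mitfa} mutant; the double mutant matches the \emph{sox10} mutant;
#' and \emph{sox10} transcript persists at the end of the run in the
#' \emph{mitfa} mutant but not in wild type. Contract violations are reported
#' per clause (not thrown) so parameter sweeps can tally them.
#'
#' @inheritParams grn_integrate
#' @param theta_det detection threshold (nM).
#' @return object of class \code{grn_panel}: trajectories (one per genotype),
#'   a metrics data.frame (duration above threshold and peak per readout
#'   species and genotype), and a named logical \code{contracts} vector.
#' @examples
#' pan <- run_panel("C", grn_params(), dt = 0.05)
#' pan$contracts
#' @export
run_panel <- function(variant = "C", params = grn_params(),
                      t0 = 0, t1 = 96, dt = 0.01, theta_det = 0.01) {
  genos <- list(WT = genotype_wt(),
                mitfa = genotype_mitfa_null(),
                sox10 = genotype_sox10_null(),
                double = genotype_double_null())
  trajs <- lapply(genos, function(g) {
    grn_integrate(variant, params, g, t0 = t0, t1 = t1, dt = dt)
  })

  readouts <- c("S", "M", "D", "T")
  metrics <- do.call(rbind, lapply(names(trajs), function(nm) {
    tr <- trajs[[nm]]
    data.frame(genotype = nm, species = readouts,
               duration_above_hr = vapply(readouts, function(sp) {
                 duration_above(tr, sp, theta_det)
               }, numeric(1)),
               peak_nM = vapply(readouts, function(sp) peak_level(tr, sp), numeric(1)),
               final_nM = vapply(readouts, function(sp) {
                 trajectory_species(tr, sp)[length(tr$times)]
               }, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  m <- function(g, sp, col) metrics[metrics$genotype == g & metrics$species == sp, col]
  dD <- c(mitfa = m("mitfa", "D", "duration_above_hr"),
          sox10 = m("sox10", "D", "duration_above_hr"),
          double = m("double", "D", "duration_above_hr"))
  pD <- c(mitfa = m("mitfa", "D", "peak_nM"),
          sox10 = m("sox10", "D", "peak_nM"),
          double = m("double", "D", "peak_nM"))
  total <- t1 - t0
  contracts <- c(
    D_transient_in_all_mutants = all(dD > 0) && all(dD < total),
    D_weakest_in_mitfa_null =
      dD[["mitfa"]] < dD[["sox10"]] && dD[["mitfa"]] < dD[["double"]] &&
      pD[["mitfa"]] < pD[["sox10"]] && pD[["mitfa"]] < pD[["double"]],
    double_matches_sox10_null =
      max(abs(trajectory_species(trajs$double, "D") -
                trajectory_species(trajs$sox10, "D"))) < 1e-9,
    sox10_persists_in_mitfa_null =
      m("mitfa", "S", "final_nM") >= theta_det,
    sox10_off_in_wt = m("WT", "S", "final_nM") < theta_det
  )

  structure(list(variant = variant, params = params, theta_det = theta_det,
                 trajectories = trajs, metrics = metrics, contracts = contracts),
            class = "grn_panel")
}

#' @export
print.grn_panel <- function(x, ...) {
  cat(sprintf("<grn_panel> Model %s, %d genotypes, theta_det = %g nM\n",
              x$variant, length(x$trajectories), x$theta_det))
  print(x$metrics, digits = 4)
  cat("contracts:\n")
  for (nm in names(x$contracts)) {
    cat(sprintf("  [%s] %s\n", if (x$contracts[[nm]]) "pass" else "FAIL", nm))
  }
  invisible(x)
}

#' Transient-Mitfa rescue of the sox10 mutant
#'
#' Supplies an exogenous pulse of functional Mitfa to the Model C
#' \emph{sox10}-null background (mimicking transient \emph{mitfa} expression
#' from the \emph{sox10} promoter) and classifies whether the network
#' converges to the differentiated "on" attractor or relaxes back "off" --
#' the bistability at the heart of the rescue observations.
#'
#' @param params a \code{\link{grn_params}} object.
#' @param mitfa_pulse a \code{\link{pulse}} of exogenous Mitfa activity.
#' @param t1 end of simulation (hpf); extended automatically to leave at
#'   least 150 hr of relaxation after the pulse plateau.
#' @param dt Euler step (hr).
#' @return list with the trajectory and \code{converged_to} (\code{"on"},
#'   \code{"off"}, or \code{NA} with a warning when the end state is close to
#'   neither attractor).
#' @examples
#' run_rescue(grn_params(), pulse(0.1, 30, 40, decay_rate = 1), dt = 0.05)$converged_to
#' @export
run_rescue <- function(params, mitfa_pulse, t1 = 96, dt = 0.01) {
  stopifnot(inherits(mitfa_pulse, "grn_pulse"))
  geno <- genotype(sox10_activity = 0, exogenous_M = mitfa_pulse)
  t_end <- max(t1, if (is.finite(mitfa_pulse$t_off)) mitfa_pulse$t_off + 150 else t1)
  tr <- grn_integrate("C", params, geno, t0 = 0, t1 = t_end, dt = dt)

  ss <- find_steady_states("C", params, genotype_sox10_null())
  stable <- Filter(function(s) isTRUE(s$stable), ss)
  M_ss <- vapply(stable, function(s) s$concentrations[["M"]], numeric(1))
  endpt <- tr$values[nrow(tr$values), ]
  dist <- vapply(stable, function(s) max(abs(endpt - s$concentrations)), numeric(1))
  near <- which.min(dist)
  scale <- max(M_ss, 0.01)
  if (dist[near] > 0.05 * scale) {
    warning("run_rescue: end state close to neither attractor (min distance ",
            signif(dist[near], 3), " nM); returning NA")
    conv <- NA_character_
  } else {
    # "on" = differentiated attractor: Mitfa above the Factor Y gate threshold
    conv <- if (M_ss[near] >= params$M_star) "on" else "off"
  }
  list(trajectory = tr, converged_to = conv,
       attractors = stable, end_state = endpt)
}

#' In-silico RNA overexpression at blastula stages
#'
#' Emulates 1-cell-stage RNA injection: exogenous Factor A and B inputs are
#' disabled (blastomeres lack the neural-crest signals) and the perturbation
#' is carried entirely by the initial Sox10/Mitfa concentrations. Readouts
#' are whether each species shows robust expression at an early and a late
#' assay point. Note these contracts encode the verbal model-consistency
#' argument about the injection experiments; the underlying study did not
#' simulate them (a documented extension).
#'
#' @param params a \code{\link{grn_params}} object.
#' @param init_S,init_M initial Sox10 / Mitfa concentrations (nM). The
#'   default dose is 10x the \code{c/d} saturation scale of the network.
#' @param t_early,t_late assay times (hr after injection), mirroring the
#'   6 and 10.5 hpf assay points.
#' @param theta_on "robust expression" threshold (nM); default 0.35, i.e. 35%
#'   of the c/d saturation level, the level of a strong in situ signal
#'   (see the methods vignette for why the in situ detection threshold
#'   theta_det is not meaningful for this fast assay).
#' @param dt Euler step (hr).
#' @return list with the trajectory and a data.frame \code{readout}
#'   (species, concentration and on/off call at each assay time).
#' @examples
#' run_overexpression(grn_params(), init_M = 10)$readout
#' @export
run_overexpression <- function(params, init_S = 0, init_M = 0,
                               t_early = 6, t_late = 10.5,
                               theta_on = 0.35, dt = 0.01) {
  stopifnot(init_S >= 0, init_M >= 0, t_early < t_late)
  p <- params
  p$pulse_A <- pulse(0)
  p$pulse_B <- pulse(0)
  init <- rep(0, length(SPECIES))
  names(init) <- SPECIES
  init["S"] <- init_S
  init["M"] <- init_M
  tr <- grn_integrate("C", p, genotype_wt(), t0 = 0, t1 = t_late, dt = dt,
                      init = init)
  at <- function(tt) vapply(SPECIES, function(sp) trajectory_at(tr, sp, tt), numeric(1))
  early <- at(t_early); late <- at(t_late)
  readout <- data.frame(species = SPECIES,
                        early_nM = unname(early), late_nM = unname(late),
                        on_early = unname(early >= theta_on),
                        on_late = unname(late >= theta_on),
                        stringsAsFactors = FALSE)
  list(trajectory = tr, readout = readout, theta_on = theta_on,
       t_early = t_early, t_late = t_late)
}

#' Hdac inhibition (Trichostatin-A-style) treatment windows
#'
#' Runs Model C with Hdac repression blocked during a treatment window,
#' paired with untreated controls, for wild type and the \emph{mitfa} null.
#' The model predicts prolonged \emph{sox10} and reduced differentiation in
#' treated wild types, and no \emph{sox10} change at all in \emph{mitfa}
#' mutants (Hdac is never recruited without Mitfa).
#'
#' @inheritParams run_rescue
#' @param window numeric \code{c(t_start, t_end)} hpf treatment window.
#' @param theta_det detection threshold (nM).
#' @return list of the four trajectories plus a summary list with
#'   \code{wt_S_at_window_end} (treated and control), D peaks, and the
#'   maximal \emph{sox10} difference between treated and control
#'   \emph{mitfa} nulls.
#' @export
run_hdac_inhibition <- function(params, window = c(24, 48), t1 = 96, dt = 0.01,
                                theta_det = 0.01) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  treat <- list(hdac_blocked_windows = if (window[1] < window[2]) list(window) else list())
  wt_ctrl <- grn_integrate("C", params, genotype_wt(), t1 = t1, dt = dt)
  wt_trt <- grn_integrate("C", params,
                          genotype(hdac_blocked_windows = treat$hdac_blocked_windows),
                          t1 = t1, dt = dt)
  mit_ctrl <- grn_integrate("C", params, genotype_mitfa_null(), t1 = t1, dt = dt)
  mit_trt <- grn_integrate("C", params,
                           genotype(mitfa_activity = 0,
                                    hdac_blocked_windows = treat$hdac_blocked_windows),
                           t1 = t1, dt = dt)
  summary <- list(
    wt_S_window_end_treated = trajectory_at(wt_trt, "S", window[2]),
    wt_S_window_end_control = trajectory_at(wt_ctrl, "S", window[2]),
    wt_D_peak_treated = peak_level(wt_trt, "D"),
    wt_D_peak_control = peak_level(wt_ctrl, "D"),
    mitfa_null_max_S_diff = max(abs(trajectory_species(mit_trt, "S") -
                                      trajectory_species(mit_ctrl, "S"))),
    theta_det = theta_det
  )
  list(wt_control = wt_ctrl, wt_treated = wt_trt,
       mitfa_null_control = mit_ctrl, mitfa_null_treated = mit_trt,
       summary = summary)
}

#' Sox9b knockdown in the sox10 mutant background
#'
#' Scales Factor Z production (Sox9b contributes to Factor Z) in the
#' \emph{sox10}-null background and compares the time-integrated dct-class
#' output -- the model analogue of residual melanin -- at full versus reduced
#' scale.
#'
#' @inheritParams run_rescue
#' @param factorZ_scale reduced Factor Z production scale in \code{[0, 1]}.
#' @param mitfa_activity mitfa activity of the background (0 gives the
#'   double-mutant background).
#' @return list with \code{auc_full}, \code{auc_reduced} (nM*hr) and the two
#'   trajectories.
#' @export
run_sox9b_knockdown <- function(params, factorZ_scale = 0.3,
                                mitfa_activity = 1, t1 = 96, dt = 0.01) {
  g_full <- genotype(sox10_activity = 0, mitfa_activity = mitfa_activity,
                     factorZ_scale = 1)
  g_red <- genotype(sox10_activity = 0, mitfa_activity = mitfa_activity,
                    factorZ_scale = factorZ_scale)
  tr_full <- grn_integrate("C", params, g_full, t1 = t1, dt = dt)
  tr_red <- grn_integrate("C", params, g_red, t1 = t1, dt = dt)
  list(auc_full = auc_species(tr_full, "D"),
       auc_reduced = auc_species(tr_red, "D"),
       factorZ_scale = factorZ_scale,
       full = tr_full, reduced = tr_red)
}
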