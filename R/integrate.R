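#' Simulate a model by explicit Euler integration
#'
#' Fixed-step forward Euler on the GRN right-hand side, the integration
#' scheme the models were built around. Any negative intermediate (possible
#' from Euler undershoot near zero) is clipped to 0 and the clip events are
#' counted. A step that would change a species by more than 50% of its bound
#' \code{c_g/d_g} aborts with a stability error naming the species.
#'
#' @inheritParams grn_rhs
#' @param t0,t1 start and end times (hpf).
#' @param dt Euler step (hr), default 0.01.
#' @param init initial state (length-7, non-negative), default all zero.
#' @return object of class \code{grn_trajectory}: list with \code{times}
#'   (hpf), \code{values} (matrix, one column per species, nM),
#'   \code{variant}, \code{genotype}, \code{params}, \code{dt},
#'   \code{clip_count}.
#' @examples
#' tr <- grn_integrate("C", grn_params(), t1 = 48, dt = 0.05)
#' tail(as.data.frame(tr))
#' @export
grn_integrate <- function(variant, params, geno = genotype_wt(),
                          t0 = 0, t1 = 96, dt = 0.01, init = NULL,
                          soft_gates = FALSE) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  stopifnot(inherits(params, "grn_params"))
  if (dt <= 0) stop("grn_integrate: dt must be positive")
  if (t1 <= t0) stop("grn_integrate: t1 must exceed t0")
  if (is.null(init)) init <- rep(0, length(SPECIES))
  y <- as_state(init)
  if (any(y < 0)) stop("grn_integrate: initial state must be non-negative")

  n_steps <- round((t1 - t0) / dt)
  times <- t0 + dt * (0:n_steps)
  rhs <- make_rhs(variant, params, geno, soft_gates = soft_gates)

  # per-species stability bound: 50% of the saturation level c_g/d_g
  vp <- variant_params(params, variant)$params
  cg <- unlist(vp[paste0("c_", SPECIES)], use.names = FALSE)
  dg <- unlist(vp[paste0("d_", SPECIES)], use.names = FALSE)
  bound <- ifelse(dg > 0, cg / dg, Inf)
  max_step <- 0.5 * bound

  values <- matrix(NA_real_, nrow = n_steps + 1, ncol = length(SPECIES),
                   dimnames = list(NULL, SPECIES))
  values[1, ] <- y
  clip_count <- 0L
  for (i in seq_len(n_steps)) {
    d <- rhs(times[i], y)
    delta <- dt * d
    too_big <- abs(delta) > max_step & is.finite(max_step) & max_step > 0
    if (any(too_big)) {
      stop("grn_integrate: dt = ", dt, " unstable for species ",
           paste(SPECIES[too_big], collapse = ","),
           " (step exceeds 50% of c/d bound); reduce dt")
    }
    y <- y + delta
    neg <- y < 0
    if (any(neg)) {
      clip_count <- clip_count + sum(neg)
      y[neg] <- 0
    }
    values[i + 1, ] <- y
  }

  structure(list(variant = variant, genotype = geno, params = params,
                 times = times, values = values, dt = dt,
                 clip_count = clip_count),
            class = "grn_trajectory")
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat(sprintf("<grn_trajectory> Model %s, %d points on [%g, %g] hpf (dt = %g hr)\n",
              x$variant, length(x$times), x$times[1],
              x$times[length(x$times)], x$dt))
  fin <- x$values[nrow(x$values), ]
  cat("  final state (nM):",
      paste(sprintf("%s=%.4g", SPECIES, fin), collapse = " "), "\n")
  if (x$clip_count > 0) cat("  negative clips:", x$clip_count, "\n")
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x a \code{grn_trajectory}.
#' @param row.names,optional,... ignored (base generic signature).
#' @return data.frame with columns \code{time_hpf}, \code{species},
#'   \code{concentration_nM}, \code{genotype}, \code{variant}.
#' @export
as.data.frame.grn_trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  g <- x$genotype
  glab <- genotype_label(g)
  data.frame(
    time_hpf = rep(x$times, times = length(SPECIES)),
    species = rep(SPECIES, each = length(x$times)),
    concentration_nM = as.vector(x$values),
    genotype = glab,
    variant = x$variant,
    stringsAsFactors = FALSE
  )
}

genotype_label <- function(g) {
  base <- if (g$sox10_activity == 0 && g$mitfa_activity == 0) "sox10;mitfa"
  else if (g$sox10_activity == 0) "sox10"
  else if (g$mitfa_activity == 0) "mitfa"
  else "WT"
  extras <- c(
    if (g$factorZ_scale < 1) sprintf("sox9bMO(%.2g)", g$factorZ_scale),
    if (length(g$hdac_blocked_windows) > 0) "hdac-inhibited",
    if (!is.null(g$exogenous_M)) "+Mitfa",
    if (!is.null(g$exogenous_S)) "+Sox10"
  )
  paste(c(base, extras), collapse = " ")
}

#' Extract one species series from a trajectory
#'
#' @param traj a \code{grn_trajectory}.
#' @param species one of \code{S, M, H, Y, Z, D, T}.
#' @return numeric vector aligned with \code{traj$times}.
#' @export
trajectory_species <- function(traj, species) {
  stopifnot(inherits(traj, "grn_trajectory"))
  species <- match.arg(species, SPECIES)
  traj$values[, species]
}

#' Interpolate a trajectory at arbitrary times
#'
#' Linear interpolation of one species' concentration series.
#'
#' @inheritParams trajectory_species
#' @param t times (hpf), must lie within the trajectory range.
#' @return concentrations (nM) at \code{t}.
#' @export
trajectory_at <- function(traj, species, t) {
  stopifnot(inherits(traj, "grn_trajectory"))
  rng <- range(traj$times)
  if (any(t < rng[1] - 1e-9 | t > rng[2] + 1e-9)) {
    stop("trajectory_at: requested times outside the trajectory range")
  }
  approx(traj$times, trajectory_species(traj, species), xout = t, rule = 2)$y
}

#' Plot a trajectory
#'
#' Base-graphics line plot of all (or selected) species against time.
#'
#' @param x a \code{grn_trajectory}.
#' @param species subset of species to draw (default all).
#' @param log_y plot concentrations on a log axis.
#' @param ... passed to \code{matplot}.
#' @export
plot.grn_trajectory <- function(x, species = SPECIES, log_y = FALSE, ...) {
  species <- match.arg(species, SPECIES, several.ok = TRUE)
  v <- x$values[, species, drop = FALSE]
  if (log_y) v <- pmax(v, 1e-8)
  graphics::matplot(x$times, v, type = "l", lty = 1,
                    xlab = "time (hpf)", ylab = "concentration (nM)",
                    log = if (log_y) "y" else "",
                    main = sprintf("Model %s, %s", x$variant,
                                   genotype_label(x$genotype)), ...)
  graphics::legend("topright", legend = species, lty = 1,
                   col = seq_along(species), bty = "n")
  invisible(x)
}

#' Export a trajectory as tidy CSV
#'
#' @param traj a \code{grn_trajectory}.
#' @param path output file path.
#' @param thin keep every \code{thin}-th time point (default 1 = all).
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, thin = 1L) {
  df <- as.data.frame(traj)
  if (thin > 1L) {
    keep <- traj$times[seq(1, length(traj$times), by = thin)]
    df <- df[df$time_hpf %in% keep, ]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
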