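# Evaluate an expression with a locally seeded RNG, restoring the caller's
# RNG state afterwards (deterministic under the given seed, no side effects).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic per-embryo cell scoring of detectable expression
#'
#' Emulates the in situ scoring readout: at each time point,
#' \code{cells_per_fish} pigmented cells from each of \code{n_fish} embryos
#' are scored positive when their (noisy) expression level reaches the
#' detection threshold. Each cell draws an independent lognormal multiplier
#' with median 1 and coefficient of variation \code{cv} (cell-to-cell
#' variation in transcript level and stain); a cell is positive iff
#' \code{m * x(t) >= theta_det}. Counts are therefore binomial per time point
#' with a trajectory-dependent success probability.
#'
#' @param traj trajectory supplying the underlying expression level.
#' @param species scored species (default \code{"S"}, the sox10 readout).
#' @param times scored time points (hpf); the default brackets the window in
#'   which melanocytes go from all-positive to none.
#' @param n_fish embryos per time point.
#' @param cells_per_fish scored cells per embryo.
#' @param theta_det detection threshold (nM).
#' @param cv per-cell lognormal coefficient of variation (0 = noise-free).
#' @param seed RNG seed; identical seed and configuration give identical
#'   counts.
#' @return object of class \code{grn_cell_scoring}: data.frame with columns
#'   \code{time_hpf}, \code{n_positive}, \code{n_total},
#'   \code{percent_positive}, plus the configuration as attributes.
#' @examples
#' tr <- grn_integrate("C", grn_params(), dt = 0.05)
#' score_cells(tr, seed = 1)
#' @export
score_cells <- function(traj, species = "S",
                        times = seq(30, 51, by = 3),
                        n_fish = 5, cells_per_fish = 20,
                        theta_det = 0.01, cv = 0.3, seed = 1) {
  stopifnot(inherits(traj, "grn_trajectory"), cv >= 0,
            n_fish >= 1, cells_per_fish >= 1)
  x <- trajectory_at(traj, species, times)
  n_total <- n_fish * cells_per_fish
  sdlog <- sqrt(log(1 + cv^2))
  counts <- with_seed(seed, {
    vapply(x, function(xi) {
      m <- if (cv == 0) rep(1, n_total) else rlnorm(n_total, meanlog = 0, sdlog = sdlog)
      sum(m * xi >= theta_det)
    }, numeric(1))
  })
  df <- data.frame(time_hpf = times, n_positive = as.integer(counts),
                   n_total = n_total,
                   percent_positive = 100 * counts / n_total)
  structure(df, class = c("grn_cell_scoring", "data.frame"),
            species = species, theta_det = theta_det, cv = cv, seed = seed,
            n_fish = n_fish, cells_per_fish = cells_per_fish)
}

#' Synthetic qPCR-style fold-change table
#'
#' Emulates the fold-change-versus-wild-type readout: for each mutant
#' genotype in a panel, replicates of
#' \code{100 * x_genotype(t) / x_WT(t) * exp(N(0, cv))} -- percent of
#' wild-type expression with multiplicative (log-scale) noise.
#'
#' @param panel a \code{\link{run_panel}} result.
#' @param gene readout species: \code{"M"} (mitfa), \code{"D"} (dct-class) or
#'   \code{"T"} (tyrp1b).
#' @param time assay time (hpf), within the panel grid.
#' @param n_reps replicates per genotype.
#' @param cv log-scale noise standard deviation (0 = exact ratios).
#' @param seed RNG seed.
#' @return data.frame with columns \code{gene}, \code{genotype},
#'   \code{time_hpf}, \code{replicate}, \code{percent_of_wt}.
#' @export
qpcr_foldchange <- function(panel, gene = c("M", "D", "T"), time = 30,
                            n_reps = 3, cv = 0.2, seed = 1) {
  stopifnot(inherits(panel, "grn_panel"))
  gene <- match.arg(gene)
  x_wt <- trajectory_at(panel$trajectories$WT, gene, time)
  if (x_wt == 0) stop("qpcr_foldchange: wild-type level is 0 at t = ", time,
                      "; fold change undefined")
  genos <- names(panel$trajectories)
  rows <- with_seed(seed, {
    do.call(rbind, lapply(genos, function(g) {
      x_g <- trajectory_at(panel$trajectories[[g]], gene, time)
      noise <- if (cv == 0) rep(1, n_reps) else exp(rnorm(n_reps, 0, cv))
      data.frame(gene = gene, genotype = g, time_hpf = time,
                 replicate = seq_len(n_reps),
                 percent_of_wt = 100 * (x_g / x_wt) * noise,
                 stringsAsFactors = FALSE)
    }))
  })
  rows
}

#' Write a versioned synthetic-observation fixture bundle
#'
#' Generates, from the reference Model C configuration, a wild-type cell
#' scoring series for the sox10 and mitfa readouts and a mutant-panel
#' fold-change table, and writes them as CSV files with a JSON manifest
#' (seed, configuration hash). Identical seed and configuration give
#' byte-identical bundles.
#'
#' @param seed RNG seed controlling all noise draws.
#' @param dir output directory (created if needed).
#' @param params model parameters (default reference set).
#' @param dt Euler step used for the underlying runs.
#' @return invisibly, a list with the file paths and the manifest.
#' @export
make_fixture <- function(seed, dir, params = grn_params(), dt = 0.02) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tr <- grn_integrate("C", params, genotype_wt(), dt = dt)
  cells_S <- score_cells(tr, "S", seed = seed)
  cells_M <- score_cells(tr, "M", seed = seed + 1)
  cells <- rbind(cbind(species = "S", as.data.frame(unclass(cells_S),
                                                   stringsAsFactors = FALSE)),
                 cbind(species = "M", as.data.frame(unclass(cells_M),
                                                   stringsAsFactors = FALSE)))
  panel <- run_panel("C", params, dt = dt)
  fc <- qpcr_foldchange(panel, "D", time = 30, seed = seed + 2)

  cfg <- list(seed = seed, dt = dt,
              params = serialize_params(params))
  manifest <- list(seed = seed, dt = dt, config_hash = config_hash(cfg),
                   files = c("cell_scoring.csv", "foldchange.csv"))

  paths <- list(cells = file.path(dir, "cell_scoring.csv"),
                foldchange = file.path(dir, "foldchange.csv"),
                manifest = file.path(dir, "manifest.json"))
  ok <- tryCatch({
    write.csv(cells, paths$cells, row.names = FALSE)
    write.csv(fc, paths$foldchange, row.names = FALSE)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               paths$manifest)
    TRUE
  }, error = function(e) {
    stop("make_fixture: failed writing to ", dir, ": ", conditionMessage(e))
  })
  invisible(list(paths = paths, manifest = manifest))
}

#' Read back a fixture bundle
#'
#' @param dir directory written by \code{\link{make_fixture}}.
#' @return list with \code{cells}, \code{foldchange} data.frames and the
#'   parsed \code{manifest}.
#' @export
read_fixture <- function(dir) {
  list(cells = read.csv(file.path(dir, "cell_scoring.csv"),
                        stringsAsFactors = FALSE),
       foldchange = read.csv(file.path(dir, "foldchange.csv"),
                             stringsAsFactors = FALSE),
       manifest = jsonlite::fromJSON(file.path(dir, "manifest.json")))
}
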