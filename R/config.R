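# ---- serialization of parameters / genotypes / pulses -----------------------

pulse_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  list(amplitude = p$amplitude, t_on = p$t_on,
       t_off = if (is.finite(p$t_off)) p$t_off else "inf",
       decay_rate = p$decay_rate)
}

pulse_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  t_off <- x$t_off
  if (is.character(t_off)) t_off <- Inf
  pulse(amplitude = x$amplitude,
        t_on = if (is.null(x$t_on)) 0 else x$t_on,
        t_off = if (is.null(t_off)) Inf else t_off,
        decay_rate = if (is.null(x$decay_rate)) 0 else x$decay_rate)
}

#' Serialize parameters to a flat key-value list
#'
#' Stable structured-text representation of a parameter set: one numeric
#' entry per scalar parameter, plus \code{pulse_A}/\code{pulse_B} blocks.
#' Round-trips through \code{\link{deserialize_params}} and YAML.
#'
#' @param params a \code{\link{grn_params}} object.
#' @return named list suitable for \code{yaml::as.yaml}.
#' @export
serialize_params <- function(params) {
  stopifnot(inherits(params, "grn_params"))
  out <- lapply(PARAM_SCALARS, function(nm) params[[nm]])
  names(out) <- PARAM_SCALARS
  out$pulse_A <- pulse_to_list(params$pulse_A)
  out$pulse_B <- pulse_to_list(params$pulse_B)
  out
}

#' @rdname serialize_params
#' @param x a list as produced by \code{serialize_params} (e.g. parsed from
#'   YAML); missing keys fall back to the reference defaults.
#' @export
deserialize_params <- function(x) {
  unknown <- setdiff(names(x), c(PARAM_SCALARS, "pulse_A", "pulse_B"))
  if (length(unknown) > 0) {
    stop("deserialize_params: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  args <- x[intersect(names(x), PARAM_SCALARS)]
  for (nm in c("pulse_A", "pulse_B")) {
    if (!is.null(x[[nm]])) args[[nm]] <- pulse_from_list(x[[nm]])
  }
  do.call(grn_params, args)
}

genotype_to_list <- function(g) {
  list(sox10_activity = g$sox10_activity,
       mitfa_activity = g$mitfa_activity,
       factorZ_scale = g$factorZ_scale,
       hdac_blocked_windows = lapply(g$hdac_blocked_windows, as.numeric),
       exogenous_M = pulse_to_list(g$exogenous_M),
       exogenous_S = pulse_to_list(g$exogenous_S))
}

genotype_from_list <- function(x) {
  if (is.null(x)) return(genotype_wt())
  allowed <- c("sox10_activity", "mitfa_activity", "factorZ_scale",
               "hdac_blocked_windows", "exogenous_M", "exogenous_S")
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    stop("genotype block: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  genotype(
    sox10_activity = if (is.null(x$sox10_activity)) 1 else x$sox10_activity,
    mitfa_activity = if (is.null(x$mitfa_activity)) 1 else x$mitfa_activity,
    factorZ_scale = if (is.null(x$factorZ_scale)) 1 else x$factorZ_scale,
    hdac_blocked_windows = if (is.null(x$hdac_blocked_windows)) list()
      else lapply(x$hdac_blocked_windows, as.numeric),
    exogenous_M = pulse_from_list(x$exogenous_M),
    exogenous_S = pulse_from_list(x$exogenous_S)
  )
}

# ---- run configuration -------------------------------------------------------

CONFIG_TOP_KEYS <- c("variant", "params", "genotype", "integration",
                     "thresholds", "rescue", "overexpression", "hdac",
                     "knockdown", "sweep", "synth", "seed")

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration (model variant, parameter overrides,
#' genotype block, integration grid, thresholds, scenario-specific blocks,
#' seed), rejecting unknown keys with field-level messages, and resolves it
#' against the package defaults.
#'
#' @param path YAML file path.
#' @param overrides named list of \code{block$key} overrides applied after
#'   parsing (names like \code{"integration.dt"}).
#' @return object of class \code{grn_config}: the resolved configuration,
#'   with \code{params} and \code{genotype} constructed, and a content hash.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  if (length(overrides) > 0) {
    for (key in names(overrides)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (length(parts) == 1) raw[[parts]] <- overrides[[key]]
      else raw[[parts[1]]][[parts[2]]] <- overrides[[key]]
    }
  }
  resolve_run_config(raw)
}

resolve_run_config <- function(raw) {
  unknown <- setdiff(names(raw), CONFIG_TOP_KEYS)
  if (length(unknown) > 0) {
    stop("config: unknown top-level key(s): ", paste(unknown, collapse = ", "))
  }
  variant <- if (is.null(raw$variant)) "C" else match.arg(raw$variant, MODEL_VARIANTS)
  params <- deserialize_params(if (is.null(raw$params)) list() else raw$params)
  geno <- genotype_from_list(raw$genotype)

  check_block <- function(block, allowed, name) {
    if (is.null(block)) return(list())
    unknown <- setdiff(names(block), allowed)
    if (length(unknown) > 0) {
      stop("config: unknown key(s) in '", name, "': ",
           paste(unknown, collapse = ", "))
    }
    block
  }
  integration <- utils::modifyList(list(t0 = 0, t1 = 96, dt = 0.01),
    check_block(raw$integration, c("t0", "t1", "dt"), "integration"))
  thresholds <- utils::modifyList(list(theta_det = 0.01, r_min = 5, t_late = 60),
    check_block(raw$thresholds, c("theta_det", "r_min", "t_late"), "thresholds"))
  rescue <- check_block(raw$rescue, c("amplitude", "t_on", "t_off", "decay_rate"),
                        "rescue")
  overexpression <- check_block(raw$overexpression,
                                c("init_S", "init_M", "t_early", "t_late",
                                  "theta_on"), "overexpression")
  hdac <- check_block(raw$hdac, c("window_start", "window_end"), "hdac")
  knockdown <- check_block(raw$knockdown, c("factorZ_scale", "mitfa_activity"),
                           "knockdown")
  sweep_blk <- check_block(raw$sweep, c("param_x", "param_y", "fold_range",
                                        "n_grid"), "sweep")
  synth <- check_block(raw$synth, c("species", "n_fish", "cells_per_fish",
                                    "cv", "times"), "synth")
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)

  cfg <- list(variant = variant, params = params, genotype = geno,
              integration = integration, thresholds = thresholds,
              rescue = rescue, overexpression = overexpression, hdac = hdac,
              knockdown = knockdown, sweep = sweep_blk, synth = synth,
              seed = seed)
  cfg$hash <- config_hash(resolved_config_list(cfg))
  structure(cfg, class = "grn_config")
}

# Canonical plain-list form of a resolved config (serializable, hashable).
resolved_config_list <- function(cfg) {
  list(variant = cfg$variant,
       params = serialize_params(cfg$params),
       genotype = genotype_to_list(cfg$genotype),
       integration = cfg$integration, thresholds = cfg$thresholds,
       rescue = cfg$rescue, overexpression = cfg$overexpression,
       hdac = cfg$hdac, knockdown = cfg$knockdown, sweep = cfg$sweep,
       synth = cfg$synth, seed = cfg$seed)
}

#' Content hash of a configuration-like list
#'
#' MD5 of the canonical JSON serialization; used to tie outputs to the exact
#' configuration that produced them.
#'
#' @param x a serializable list.
#' @return 32-character hex string.
#' @export
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15, null = "null"),
             tmp)
  unname(tools::md5sum(tmp))
}

# Atomic-ish write: write to a temp file in the target directory, then rename.
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

# ---- the config-driven runner ------------------------------------------------

RUN_SUBCOMMANDS <- c("simulate", "steady", "panel", "rescue", "overexpress",
                     "hdac", "knockdown", "sweep", "synth", "fixtures")

#' Run one analysis subcommand from a configuration file
#'
#' The config-driven entry point tying all modules together (also exposed as
#' the \code{inst/cli/melgrn.R} command-line script). Each subcommand writes
#' its artifacts (tidy CSV trajectories, JSON summaries including the
#' resolved configuration hash and seed) into \code{out_dir}. Contract
#' failures in the panel subcommand are results reported in the summary, not
#' errors.
#'
#' @param subcommand one of \code{simulate, steady, panel, rescue,
#'   overexpress, hdac, knockdown, sweep, synth, fixtures}.
#' @param config_path path to a YAML run configuration
#'   (see \code{\link{read_run_config}}); shipped reference configurations
#'   live under \code{system.file("extdata/configs", package = "melGRN")}.
#' @param out_dir output directory, created if needed.
#' @param overrides named list of overrides, names like
#'   \code{"integration.dt"}.
#' @return invisibly, the summary list written to \code{summary.json}.
#' @export
run_command <- function(subcommand, config_path, out_dir,
                        overrides = list()) {
  subcommand <- match.arg(subcommand, RUN_SUBCOMMANDS)
  cfg <- read_run_config(config_path, overrides)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  ig <- cfg$integration
  th <- cfg$thresholds
  summary <- list(subcommand = subcommand, config_hash = cfg$hash,
                  seed = cfg$seed, variant = cfg$variant,
                  package_version = as.character(utils::packageVersion("melGRN")))

  emit_traj <- function(tr, name) {
    write_atomic(function(p) write_trajectory_csv(tr, p, thin = 10L),
                 file.path(out_dir, paste0(name, ".csv")))
  }

  if (subcommand == "simulate") {
    tr <- grn_integrate(cfg$variant, cfg$params, cfg$genotype,
                        t0 = ig$t0, t1 = ig$t1, dt = ig$dt)
    fl <- behaviour_flags(tr, th$theta_det, th$t_late, th$r_min)
    emit_traj(tr, "trajectory")
    summary$flags <- unclass(fl)
    summary$clip_count <- tr$clip_count
  } else if (subcommand == "steady") {
    ss <- find_steady_states(cfg$variant, cfg$params, cfg$genotype)
    summary$steady_states <- lapply(ss, function(s) {
      list(concentrations = as.list(s$concentrations),
           regime = as.list(s$regime), stable = s$stable,
           residual = s$residual)
    })
  } else if (subcommand == "panel") {
    pan <- run_panel(cfg$variant, cfg$params, t0 = ig$t0, t1 = ig$t1,
                     dt = ig$dt, theta_det = th$theta_det)
    for (nm in names(pan$trajectories)) emit_traj(pan$trajectories[[nm]], nm)
    write_atomic(function(p) write.csv(pan$metrics, p, row.names = FALSE),
                 file.path(out_dir, "metrics.csv"))
    summary$contracts <- as.list(pan$contracts)
  } else if (subcommand == "rescue") {
    rb <- cfg$rescue
    pl <- pulse(amplitude = if (is.null(rb$amplitude)) 0.1 else rb$amplitude,
                t_on = if (is.null(rb$t_on)) 30 else rb$t_on,
                t_off = if (is.null(rb$t_off)) 40 else rb$t_off,
                decay_rate = if (is.null(rb$decay_rate)) 1 else rb$decay_rate)
    res <- run_rescue(cfg$params, pl, t1 = ig$t1, dt = ig$dt)
    emit_traj(res$trajectory, "trajectory")
    summary$converged_to <- res$converged_to
  } else if (subcommand == "overexpress") {
    ob <- cfg$overexpression
    res <- do.call(run_overexpression, c(list(params = cfg$params, dt = ig$dt), ob))
    write_atomic(function(p) write.csv(res$readout, p, row.names = FALSE),
                 file.path(out_dir, "readout.csv"))
    summary$readout <- res$readout
  } else if (subcommand == "hdac") {
    hb <- cfg$hdac
    win <- c(if (is.null(hb$window_start)) 24 else hb$window_start,
             if (is.null(hb$window_end)) 48 else hb$window_end)
    res <- run_hdac_inhibition(cfg$params, win, t1 = ig$t1, dt = ig$dt,
                               theta_det = th$theta_det)
    for (nm in setdiff(names(res), "summary")) emit_traj(res[[nm]], nm)
    summary$hdac <- res$summary
  } else if (subcommand == "knockdown") {
    kb <- cfg$knockdown
    res <- run_sox9b_knockdown(
      cfg$params,
      factorZ_scale = if (is.null(kb$factorZ_scale)) 0.3 else kb$factorZ_scale,
      mitfa_activity = if (is.null(kb$mitfa_activity)) 1 else kb$mitfa_activity,
      t1 = ig$t1, dt = ig$dt)
    summary$auc_full <- res$auc_full
    summary$auc_reduced <- res$auc_reduced
  } else if (subcommand == "sweep") {
    sb <- cfg$sweep
    if (is.null(sb$param_x)) {
      pair <- default_sweep_pairs(cfg$variant)[[1]]
      sb$param_x <- pair[1]; sb$param_y <- pair[2]
    }
    sw <- sweep_pairwise(cfg$variant, sb$param_x, sb$param_y,
                         fold_range = if (is.null(sb$fold_range)) 100 else sb$fold_range,
                         n_grid = if (is.null(sb$n_grid)) 21 else sb$n_grid,
                         base_params = cfg$params, t0 = ig$t0, t1 = ig$t1,
                         dt = max(ig$dt, 0.05),
                         theta_det = th$theta_det, r_min = th$r_min)
    write_atomic(function(p) write.csv(as.data.frame(sw), p, row.names = FALSE),
                 file.path(out_dir, "sweep.csv"))
    summary$acceptable_fraction <- acceptable_fraction(sw, th$theta_det, th$r_min)
    summary$param_x <- sw$param_x; summary$param_y <- sw$param_y
  } else if (subcommand == "synth") {
    sb <- cfg$synth
    tr <- grn_integrate(cfg$variant, cfg$params, cfg$genotype,
                        t0 = ig$t0, t1 = ig$t1, dt = ig$dt)
    cs <- score_cells(tr,
                      species = if (is.null(sb$species)) "S" else sb$species,
                      times = if (is.null(sb$times)) seq(30, 51, by = 3)
                        else as.numeric(sb$times),
                      n_fish = if (is.null(sb$n_fish)) 5 else sb$n_fish,
                      cells_per_fish = if (is.null(sb$cells_per_fish)) 20
                        else sb$cells_per_fish,
                      theta_det = th$theta_det,
                      cv = if (is.null(sb$cv)) 0.3 else sb$cv,
                      seed = cfg$seed)
    write_atomic(function(p) write.csv(as.data.frame(unclass(cs)), p,
                                       row.names = FALSE),
                 file.path(out_dir, "cell_scoring.csv"))
    summary$percent_positive <- cs$percent_positive
  } else if (subcommand == "fixtures") {
    fx <- make_fixture(cfg$seed, out_dir, params = cfg$params,
                       dt = max(ig$dt, 0.02))
    summary$manifest <- fx$manifest
  }

  write_atomic(function(p) {
    yaml::write_yaml(resolved_config_list(cfg), p)
  }, file.path(out_dir, "resolved_config.yaml"))
  write_atomic(function(p) {
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                                digits = 12, null = "null", na = "null"), p)
  }, file.path(out_dir, "summary.json"))
  invisible(summary)
}
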