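#' Default pipeline configuration
#'
#' Nested list of all protocol parameters: 3 Angstrom cluster cutoff,
#' 10 ns MSM lag, 1 Angstrom grid spacing at 300 K with a 1 kcal/mol
#' reporting contour, 20 Angstrom unbound and 3 Angstrom bound macrostate
#' cutoffs, and 50% pathway flux fraction. Data-volume parameters (frame
#' spacing, clustering stride, convergence checkpoint interval) default to
#' the scale of the bundled toy binding simulator so the whole pipeline
#' runs out of the box; for production MD data set `frame_spacing` to the
#' trajectory spacing and scale `clustering.stride` and
#' `convergence.interval_us` accordingly (e.g. 10 microsecond checkpoints
#' for hundreds of microseconds of aggregate data).
#'
#' @return a nested configuration list.
#' @export
default_config <- function() {
  list(
    paths = list(trajectories = NULL, topology = NULL, reference = NULL,
                 outdir = "msmpose_out"),
    frame_spacing = 1,
    clustering = list(cutoff = 3, stride = 8L, rng_seed = 1L,
                      n_medoid_iter = 3L),
    msm = list(lag = 10, lags = c(2, 4, 10, 20), mode = "reversible-mle",
               sliding = TRUE),
    grid = list(spacing = 1, temperature = 300, contour = 1.0),
    tpt = list(unbound = 20, bound = 3, pathway_fraction = 0.5),
    convergence = list(interval_us = 2, tolerance = 0.5),
    seeding = list(policy = "uniform-states", n_seeds = 10L, rng_seed = 1L),
    simulate = list(n_steps = 20000L, n_traj = 20L, stride = 25L,
                    step_ns = 0.04, rng_seed = 1L, box_halfwidth = 28,
                    temperature = 300)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default. The merged configuration is validated.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- modify_list_deep(cfg, user)
  }
  validate_config(cfg)
  cfg
}

modify_list_deep <- function(base, upd) {
  for (k in names(upd)) {
    if (is.list(base[[k]]) && is.list(upd[[k]]))
      base[[k]] <- modify_list_deep(base[[k]], upd[[k]])
    else base[[k]] <- upd[[k]]
  }
  base
}

validate_config <- function(cfg) {
  need_pos <- list("frame_spacing" = cfg$frame_spacing,
                   "clustering.cutoff" = cfg$clustering$cutoff,
                   "clustering.stride" = cfg$clustering$stride,
                   "msm.lag" = cfg$msm$lag,
                   "grid.spacing" = cfg$grid$spacing,
                   "grid.temperature" = cfg$grid$temperature,
                   "tpt.unbound" = cfg$tpt$unbound,
                   "tpt.bound" = cfg$tpt$bound,
                   "tpt.pathway_fraction" = cfg$tpt$pathway_fraction,
                   "convergence.interval_us" = cfg$convergence$interval_us,
                   "convergence.tolerance" = cfg$convergence$tolerance)
  for (k in names(need_pos)) {
    v <- need_pos[[k]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("invalid config value for key ", k, ": must be a positive number")
  }
  r <- cfg$msm$lag / cfg$frame_spacing
  if (abs(r - round(r)) > 1e-9 || r < 1 - 1e-9)
    stop("invalid config value for key msm.lag: must be a positive integer ",
         "multiple of the frame spacing (", cfg$frame_spacing, " ns)")
  invisible(cfg)
}

log_line <- function(outdir, level, stage, ...) {
  msg <- sprintf("%s %s stage=%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 level, stage, paste(..., collapse = " "))
  message(msg)
  cat(msg, "\n", file = file.path(outdir, "msmpose.log"), append = TRUE)
}

artifact <- function(outdir, name) file.path(outdir, name)

require_artifact <- function(outdir, name, producer) {
  p <- artifact(outdir, name)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s'; run stage '%s' first", name, producer))
  p
}

update_manifest <- function(outdir, files) {
  mpath <- artifact(outdir, "manifest.json")
  manifest <- if (file.exists(mpath)) jsonlite::fromJSON(mpath) else list()
  for (f in files)
    manifest[[basename(f)]] <- unname(tools::md5sum(f))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
  invisible(mpath)
}

#' Run one pipeline stage
#'
#' Orchestrates the protocol stage by stage, each consuming the previous
#' stage's artifacts from the output directory and writing its own, plus a
#' manifest of artifact checksums and a structured log. Stages:
#' `simulate` (toy trajectories + ground truth), `cluster` (k-centers +
#' k-medoids, assignments), `msm` (counts, transition matrix, populations),
#' `timescales` (implied-timescale scan), `rank` (population ranking),
#' `fmap` (OpenDX free-energy map), `tpt` (committor/flux/pathways/MFPT),
#' `converge` (convergence series), `seed` (adaptive-sampling restarts).
#'
#' @param stage stage name (see above).
#' @param config configuration list from [load_config()].
#' @param outdir output directory (default from the config).
#' @return invisibly, a list of the artifact paths written.
#' @export
run_stage <- function(stage, config = load_config(), outdir = NULL) {
  stages <- c("simulate", "cluster", "msm", "timescales", "rank", "fmap",
              "tpt", "converge", "seed")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; expected one of ", paste(stages, collapse = ", "))
  validate_config(config)
  outdir <- outdir %||% config$paths$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  files <- switch(stage,
                  simulate = stage_simulate(config, outdir),
                  cluster = stage_cluster(config, outdir),
                  msm = stage_msm(config, outdir),
                  timescales = stage_timescales(config, outdir),
                  rank = stage_rank(config, outdir),
                  fmap = stage_fmap(config, outdir),
                  tpt = stage_tpt(config, outdir),
                  converge = stage_converge(config, outdir),
                  seed = stage_seed(config, outdir))
  update_manifest(outdir, files)
  log_line(outdir, "INFO", stage,
           sprintf("elapsed_s=%.2f artifacts=%d", as.numeric(Sys.time() - t0, units = "secs"),
                   length(files)))
  invisible(files)
}

stage_simulate <- function(config, outdir) {
  sp <- config$simulate
  spec <- toy_binding_spec(n_steps = sp$n_steps, n_traj = sp$n_traj,
                           stride = sp$stride, step_ns = sp$step_ns,
                           rng_seed = sp$rng_seed,
                           box_halfwidth = sp$box_halfwidth,
                           temperature = sp$temperature)
  sim <- simulate_toy_binding(spec)
  ens <- sim$ensemble
  top <- ens$topology
  tpath <- artifact(outdir, "topology.txt")
  write_topology(top, tpath)
  tfiles <- vapply(seq_along(ens$trajectories), function(t) {
    p <- artifact(outdir, sprintf("traj%03d.xyz", t))
    write_xyz(ens$trajectories[[t]], p, names = top$name)
    p
  }, character(1))
  rpath <- artifact(outdir, "reference_pose.xyz")
  write_xyz(sim$ground_truth$bound_pose$coords, rpath,
            names = top$name[ligand_heavy_idx(top)])
  gpath <- artifact(outdir, "ground_truth.json")
  gt <- sim$ground_truth
  gt$bound_pose <- gt$bound_pose$coords
  jsonlite::write_json(gt, gpath, auto_unbox = TRUE, digits = NA)
  log_line(outdir, "INFO", "simulate",
           sprintf("n_traj=%d frames=%d spacing_ns=%g", length(ens$trajectories),
                   n_frames(ens), ens$spacing))
  c(tpath, tfiles, rpath, gpath)
}

load_pipeline_ensemble <- function(config, outdir) {
  paths <- config$paths$trajectories
  if (is.null(paths)) {
    paths <- sort(Sys.glob(artifact(outdir, "traj*.xyz")))
    if (length(paths) == 0L)
      stop("missing artifact 'traj*.xyz'; run stage 'simulate' first (or set paths.trajectories)")
  }
  tpath <- config$paths$topology %||% require_artifact(outdir, "topology.txt", "simulate")
  read_ensemble(paths, tpath, config$frame_spacing)
}

load_reference_pose <- function(config, outdir, top) {
  rpath <- config$paths$reference %||% require_artifact(outdir, "reference_pose.xyz", "simulate")
  coords <- read_xyz(rpath, length(ligand_heavy_idx(top)))[, , 1]
  ligand_pose(coords, top)
}

stage_cluster <- function(config, outdir) {
  ens <- load_pipeline_ensemble(config, outdir)
  cc <- config$clustering
  cm <- kcenters(ens, cutoff = cc$cutoff, stride = cc$stride)
  cm <- kmedoids_refine(cm, ens, n_iter = cc$n_medoid_iter, rng_seed = cc$rng_seed)
  full <- assign_frames(ens, cm, stride = 1L)
  apath <- artifact(outdir, "assignments.csv")
  write_assignments(full, apath)
  cpath <- artifact(outdir, "centers.csv")
  utils::write.csv(cm$centers, cpath, row.names = FALSE, quote = FALSE)
  ppath <- artifact(outdir, "centers.pdb")
  write_frames_pdb(cm$center_coords, ens$topology, ppath)
  log_line(outdir, "INFO", "cluster",
           sprintf("n_clusters=%d n_frames=%d max_dist=%.3f",
                   n_clusters(cm), nrow(full), max(cm$assignments$dist)))
  c(apath, cpath, ppath)
}

load_assignments <- function(outdir) {
  utils::read.csv(require_artifact(outdir, "assignments.csv", "cluster"))
}

stage_msm <- function(config, outdir) {
  a <- load_assignments(outdir)
  counts <- count_transitions(a, lag = config$msm$lag,
                              spacing = config$frame_spacing,
                              sliding = config$msm$sliding)
  trimmed <- ergodic_trim(counts)
  if (length(trimmed$dropped) > 0L)
    log_line(outdir, "WARN", "msm",
             sprintf("dropped_states=%s", paste(trimmed$dropped, collapse = ",")))
  model <- estimate_transition_matrix(trimmed, mode = config$msm$mode)
  cpath <- artifact(outdir, "counts.txt")
  write_matrix_sparse(trimmed, cpath)
  tpath <- artifact(outdir, "transition.txt")
  write_matrix_sparse(model, tpath)
  ppath <- artifact(outdir, "populations.csv")
  utils::write.csv(data.frame(state = seq_len(model$K),
                              orig_state = model$mapping,
                              population = sprintf("%.12g", model$pi)),
                   ppath, row.names = FALSE, quote = FALSE)
  log_line(outdir, "INFO", "msm",
           sprintf("K=%d lag_ns=%g mode=%s", model$K, model$lag, model$mode))
  c(cpath, tpath, ppath)
}

load_model <- function(config, outdir) {
  tr <- read_matrix_sparse(require_artifact(outdir, "transition.txt", "msm"))
  pops <- utils::read.csv(require_artifact(outdir, "populations.csv", "msm"))
  P <- tr$matrix
  mode <- tr$header$mode
  pi <- pops$population
  s <- sqrt(pi)
  ev <- if (mode == "reversible-mle") {
    A <- (s %o% (1 / s)) * P
    sort(eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  } else {
    e <- eigen(P, only.values = TRUE)$values
    e[order(Mod(e), decreasing = TRUE)]
  }
  model <- structure(list(P = P, pi = pi, eigenvalues = ev,
                          lag = tr$header$lag, mode = mode, K = tr$header$K,
                          mapping = pops$orig_state),
                     class = "TransitionModel")
  validate_transition_model(model)
  model
}

stage_timescales <- function(config, outdir) {
  a <- load_assignments(outdir)
  its <- implied_timescales(a, lags = config$msm$lags,
                            spacing = config$frame_spacing,
                            mode = config$msm$mode,
                            sliding = config$msm$sliding)
  path <- artifact(outdir, "timescales.csv")
  out <- its
  out$eigenvalue <- sprintf("%.12g", out$eigenvalue)
  out$timescale <- sprintf("%.12g", out$timescale)
  out$rate <- sprintf("%.12g", out$rate)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (any(its$flag != "ok"))
    log_line(outdir, "WARN", "timescales",
             sprintf("flagged=%d", sum(its$flag != "ok")))
  path
}

stage_rank <- function(config, outdir) {
  model <- load_model(config, outdir)
  rk <- rank_states(model)
  path <- artifact(outdir, "rankings.csv")
  rk$population <- sprintf("%.12g", rk$population)
  utils::write.csv(rk, path, row.names = FALSE, quote = FALSE)
  log_line(outdir, "INFO", "rank", sprintf("top_state=%d", rk$state[1]))
  path
}

stage_fmap <- function(config, outdir) {
  ens <- load_pipeline_ensemble(config, outdir)
  model <- load_model(config, outdir)
  a <- load_assignments(outdir)
  spec <- NULL   # auto-fit the box unless the config pins one
  if (!is.null(config$grid$origin) && !is.null(config$grid$dims))
    spec <- grid_spec(unlist(config$grid$origin), config$grid$spacing,
                      unlist(config$grid$dims))
  grid <- free_energy_map(model, a, ens, spec = spec,
                          spacing = config$grid$spacing,
                          temperature = config$grid$temperature)
  dxpath <- artifact(outdir, "free_energy.dx")
  write_opendx(grid, dxpath)
  csvpath <- artifact(outdir, "free_energy.csv")
  write_grid_csv(grid, csvpath)
  log_line(outdir, "INFO", "fmap",
           sprintf("occupied_cells=%d contour_kcal=%g", sum(grid$mask),
                   config$grid$contour))
  c(dxpath, csvpath)
}

stage_tpt <- function(config, outdir) {
  ens <- load_pipeline_ensemble(config, outdir)
  model <- load_model(config, outdir)
  centers <- utils::read.csv(require_artifact(outdir, "centers.csv", "cluster"))
  ref <- load_reference_pose(config, outdir, ens$topology)
  macro <- define_macrostates(model, ens, centers, ref,
                              unbound_cutoff = config$tpt$unbound,
                              bound_cutoff = config$tpt$bound)
  res <- tpt_analysis(model, macro,
                      threshold_fraction = config$tpt$pathway_fraction)
  jpath <- artifact(outdir, "tpt.json")
  cpath <- artifact(outdir, "pathways.csv")
  write_tpt(res, jpath, cpath)
  log_line(outdir, "INFO", "tpt",
           sprintf("mfpt_ns=%.4g rate_per_ns=%.4g n_pathways=%d",
                   res$mfpt, res$rate, nrow(res$pathways)))
  c(jpath, cpath)
}

stage_converge <- function(config, outdir) {
  ens <- load_pipeline_ensemble(config, outdir)
  ref <- load_reference_pose(config, outdir, ens$topology)
  cc <- config$clustering
  series <- convergence_series(ens, ref,
                               checkpoint_interval = config$convergence$interval_us,
                               cutoff = cc$cutoff, stride = cc$stride,
                               lag = config$msm$lag, mode = config$msm$mode,
                               n_medoid_iter = cc$n_medoid_iter,
                               rng_seed = cc$rng_seed,
                               tolerance = config$convergence$tolerance)
  path <- artifact(outdir, "convergence.csv")
  write_convergence(series, path)
  log_line(outdir, "INFO", "converge",
           sprintf("checkpoints=%d converged=%s", nrow(series),
                   attr(series, "converged")))
  path
}

stage_seed <- function(config, outdir) {
  ens <- load_pipeline_ensemble(config, outdir)
  model <- load_model(config, outdir)
  a <- load_assignments(outdir)
  seeds <- select_seeds(model, a, n_seeds = config$seeding$n_seeds,
                        policy = config$seeding$policy,
                        rng_seed = config$seeding$rng_seed)
  cpath <- artifact(outdir, "seeds.csv")
  utils::write.csv(seeds, cpath, row.names = FALSE, quote = FALSE)
  ppath <- artifact(outdir, "seeds.pdb")
  frames <- gather_frames(ens, seeds)
  write_frames_pdb(frames, ens$topology, ppath)
  log_line(outdir, "INFO", "seed",
           sprintf("n_seeds=%d policy=%s", nrow(seeds), config$seeding$policy))
  c(cpath, ppath)
}
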