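#' Convergence series of the top-populated pose
#'
#' Monitors the stability of the predicted pose as data accumulates: for
#' each prefix of the ensemble reaching `k * interval` of aggregate
#' simulation time, the full pipeline (k-centers clustering, k-medoids
#' refinement, MSM estimation, population ranking) is rebuilt on that
#' prefix alone and the protein-aligned ligand RMSD between the
#' top-populated state's medoid and the reference pose is recorded. The
#' rolling mean and standard deviation over a window of 2 checkpoints are
#' attached; the series is declared converged when the last two checkpoints
#' differ by less than `tolerance`.
#'
#' Without a reference pose (blind targets), supply `binding_atoms`
#' (protein atom indices, e.g. of known binding residues): the series then
#' records the minimum ligand-heavy-atom distance to those atoms instead of
#' an RMSD.
#'
#' @param ens the full [trajectory_ensemble()].
#' @param reference a [ligand_pose()], or `NULL` for blind-target mode.
#' @param checkpoint_interval aggregate-time interval between checkpoints,
#'   in microseconds (default 10).
#' @param cutoff,stride,lag,mode clustering/MSM parameters (see
#'   [kcenters()] and [build_msm()]); `lag` in ns.
#' @param n_medoid_iter k-medoids refinement passes per checkpoint.
#' @param rng_seed seed for the k-medoids proposals.
#' @param ref_frame protein frame of the reference pose (default the
#'   ensemble's first frame).
#' @param tolerance convergence tolerance in Angstrom on the last two
#'   checkpoints (default 0.5).
#' @param binding_atoms integer protein atom indices for blind-target mode.
#' @return an object of class `ConvergenceSeries`: data frame with columns
#'   `aggregate_time_us`, `value` (RMSD or distance, Angstrom),
#'   `rolling_mean`, `rolling_sd`, `n_states`; attributes `converged`,
#'   `tolerance`, `metric`.
#' @export
convergence_series <- function(ens, reference, checkpoint_interval = 10,
                               cutoff = 3, stride = 1L, lag = 10,
                               mode = "reversible-mle", n_medoid_iter = 5L,
                               rng_seed = 1L, ref_frame = NULL,
                               tolerance = 0.5, binding_atoms = NULL) {
  if (is.null(reference) && is.null(binding_atoms))
    stop("need a reference pose, or binding_atoms for blind-target mode")
  top <- ens$topology
  if (is.null(ref_frame)) ref_frame <- get_frame(ens, 1L, 1L)
  interval_ns <- checkpoint_interval * 1e3
  total_ns <- aggregate_time_ns(ens)
  n_checkpoints <- floor(total_ns / interval_ns)
  if (n_checkpoints < 1L)
    stop("ensemble holds less aggregate time than one checkpoint interval")

  ft <- frame_table(ens)
  rows <- list()
  for (k in seq_len(n_checkpoints)) {
    n_pref <- floor(k * interval_ns / ens$spacing)
    pref <- prefix_ensemble(ens, ft, n_pref)
    val <- tryCatch({
      cm <- kcenters(pref, cutoff = cutoff, stride = stride)
      cm <- kmedoids_refine(cm, pref, n_iter = n_medoid_iter, rng_seed = rng_seed)
      if (n_clusters(cm) < 2L) stop("fewer than 2 clusters")
      a_full <- assign_frames(pref, cm, stride = 1L)
      model <- build_msm(a_full, lag = lag, spacing = pref$spacing, mode = mode)
      top_state <- rank_states(model)$state[1]
      med <- cm$centers[model$mapping[top_state], ]
      fr <- get_frame(pref, med$traj, med$frame)
      if (!is.null(reference)) {
        pose_rmsd(fr, reference, ref_frame, top)
      } else {
        sup <- superpose_frame(fr, ref_frame, top)
        proxy_min_dist(sup[ligand_heavy_idx(top), , drop = FALSE],
                       ref_frame[binding_atoms, , drop = FALSE])
      }
    }, error = function(e) {
      warning(sprintf("checkpoint %d (%g us) skipped: %s", k,
                      k * checkpoint_interval, conditionMessage(e)), call. = FALSE)
      NA_real_
    })
    rows[[k]] <- data.frame(aggregate_time_us = k * checkpoint_interval,
                            value = val)
  }
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$value), , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no checkpoint could be evaluated; see the warnings for per-checkpoint causes")
  out$rolling_mean <- c(NA_real_, (out$value[-1] + out$value[-nrow(out)]) / 2)
  out$rolling_sd <- c(NA_real_, abs(out$value[-1] - out$value[-nrow(out)]) / sqrt(2))
  conv <- nrow(out) >= 2 &&
    abs(out$value[nrow(out)] - out$value[nrow(out) - 1]) < tolerance
  attr(out, "converged") <- conv
  attr(out, "tolerance") <- tolerance
  attr(out, "metric") <- if (is.null(reference)) "min_binding_distance" else "rmsd_to_reference"
  class(out) <- c("ConvergenceSeries", "data.frame")
  out
}

# first n_frames of the ensemble in linear frame order, as a new ensemble
prefix_ensemble <- function(ens, ft, n_frames_pref) {
  n_frames_pref <- min(n_frames_pref, nrow(ft))
  keep <- ft[seq_len(n_frames_pref), , drop = FALSE]
  cnt <- table(factor(keep$traj, levels = seq_along(ens$trajectories)))
  coords <- list(); ids <- character(0)
  for (t in seq_along(ens$trajectories)) {
    nk <- cnt[t]
    if (nk == 0) next
    coords[[length(coords) + 1L]] <-
      ens$trajectories[[t]][, , seq_len(nk), drop = FALSE]
    ids <- c(ids, ens$ids[t])
  }
  trajectory_ensemble(ens$topology, coords, ens$spacing, ids)
}

#' Write a convergence series as CSV
#'
#' @param series a `ConvergenceSeries`.
#' @param path output CSV (`aggregate_time_us, rmsd_A, rolling_mean,
#'   rolling_std`).
#' @export
write_convergence <- function(series, path) {
  df <- data.frame(aggregate_time_us = series$aggregate_time_us,
                   rmsd_A = series$value,
                   rolling_mean = series$rolling_mean,
                   rolling_std = series$rolling_sd)
  utils::write.csv(format(df, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select restart seeds from MSM states
#'
#' Chooses `(state, frame)` pairs to start new simulation rounds from.
#' Policy `"uniform-states"` samples states uniformly; `"inverse-counts"`
#' samples states with probability proportional to the reciprocal of their
#' total observed counts, focusing new sampling on poorly sampled states.
#' Within a chosen state a member frame is sampled uniformly.
#'
#' @param model a `TransitionModel`.
#' @param assignments assignment data frame over the frames available for
#'   restarts.
#' @param n_seeds number of restart structures to draw.
#' @param policy `"uniform-states"` or `"inverse-counts"`.
#' @param rng_seed integer seed; fixed seed gives a reproducible selection.
#' @return an object of class `SeedSet`: data frame with columns `state`
#'   (model index), `traj`, `frame`; attributes `policy`, `rng_seed`.
#' @export
select_seeds <- function(model, assignments, n_seeds,
                         policy = c("uniform-states", "inverse-counts"),
                         rng_seed = 1L) {
  policy <- match.arg(policy)
  if (n_seeds < 1L) stop("n_seeds must be >= 1")
  keep <- assignments$cluster %in% model$mapping
  a <- assignments[keep, , drop = FALSE]
  if (n_seeds > nrow(a)) stop("n_seeds exceeds the number of available frames")
  state <- match(a$cluster, model$mapping)
  counts <- tabulate(state, nbins = model$K)
  prob <- switch(policy,
                 "uniform-states" = rep(1, model$K),
                 "inverse-counts" = 1 / counts)
  prob <- prob / sum(prob)
  out <- with_seed(rng_seed, {
    st <- sample.int(model$K, n_seeds, replace = TRUE, prob = prob)
    rows <- vapply(st, function(j) {
      members <- which(state == j)
      members[sample.int(length(members), 1L)]
    }, integer(1))
    data.frame(state = st, traj = a$traj[rows], frame = a$frame[rows])
  })
  structure(out, policy = policy, rng_seed = rng_seed,
            class = c("SeedSet", "data.frame"))
}

#' Grid-translation pose seeding with steric-clash rejection
#'
#' Generates diverse near-bound and unbound starting structures from one
#' complex frame by rigidly translating the ligand to every offset of the
#' cubic lattice spanning `-box_extent .. +box_extent` Angstrom per axis at
#' `grid_step` spacing (the zero offset included), and keeping a pose only
#' if the minimum distance between any ligand heavy atom and any protein
#' atom is at least `clash_cutoff`.
#'
#' @param frame `n_atoms x 3` complex coordinates.
#' @param top the [topology()].
#' @param box_extent lattice half-width in Angstrom (default 20).
#' @param grid_step lattice spacing in Angstrom (default 5).
#' @param clash_cutoff minimum allowed ligand-protein heavy-atom distance in
#'   Angstrom (default 2).
#' @return list with `frames` (atoms x 3 x n array of surviving poses),
#'   `offsets` (n x 3 matrix), `n_rejected`.
#' @export
grid_pose_seeding <- function(frame, top, box_extent = 20, grid_step = 5,
                              clash_cutoff = 2) {
  check_frame(frame, top)
  if (grid_step <= 0) stop("grid_step must be > 0")
  heavy <- ligand_heavy_idx(top)
  lig_all <- which(top$role == "ligand")
  prot <- protein_idx(top)
  if (length(prot) == 0L) stop("topology has no protein atoms")
  # symmetric lattice always containing the zero offset (original pose)
  offs <- sort(unique(c(seq(0, -box_extent, by = -grid_step),
                        seq(0, box_extent, by = grid_step))))
  lattice <- as.matrix(expand.grid(x = offs, y = offs, z = offs))
  keep <- logical(nrow(lattice))
  P <- frame[prot, , drop = FALSE]
  H0 <- frame[heavy, , drop = FALSE]
  for (i in seq_len(nrow(lattice))) {
    H <- sweep(H0, 2, lattice[i, ], "+")
    keep[i] <- proxy_min_dist(H, P) >= clash_cutoff
  }
  if (!any(keep)) stop("no clash-free poses survive; enlarge the lattice or lower clash_cutoff")
  surv <- which(keep)
  frames <- array(0, dim = c(nrow(frame), 3L, length(surv)))
  for (k in seq_along(surv)) {
    f <- frame
    f[lig_all, ] <- sweep(frame[lig_all, , drop = FALSE], 2, lattice[surv[k], ], "+")
    frames[, , k] <- f
  }
  list(frames = frames, offsets = lattice[surv, , drop = FALSE],
       n_rejected = sum(!keep))
}
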