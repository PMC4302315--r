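#' k-centers clustering of ligand poses
#'
#' Defines structural states by farthest-point k-centers clustering under
#' the protein-aligned ligand RMSD metric: starting from a seed frame, the
#' frame farthest from all existing centers becomes the next center until
#' every (strided) frame lies within `cutoff` of some center. The k-centers
#' construction guarantees the covering radius and is a 2-approximation to
#' the optimal covering with the same number of centers.
#'
#' @param ens a [trajectory_ensemble()].
#' @param cutoff covering radius in Angstrom (default 3).
#' @param stride take every `stride`-th frame (in the ensemble's linear
#'   frame order) for clustering; remaining frames are assigned afterwards
#'   with [assign_frames()].
#' @param seed_frame integer pair `(trajectory, frame)` of the first center;
#'   default the globally first frame.
#' @return an object of class `ClusterModel`: list with `centers` (data
#'   frame `traj`,`frame`), `center_coords` (atoms x 3 x K array),
#'   `assignments` (data frame `traj`,`frame`,`cluster`,`dist` over strided
#'   frames), `cutoff`, `stride`, `topology`.
#' @export
kcenters <- function(ens, cutoff = 3, stride = 1L, seed_frame = c(1L, 1L)) {
  stopifnot(inherits(ens, "TrajectoryEnsemble"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (stride < 1L) stop("stride must be >= 1")
  ft <- frame_table(ens)
  sel <- seq(1L, nrow(ft), by = stride)
  idx <- ft[sel, , drop = FALSE]
  cube <- gather_frames(ens, idx)
  top <- ens$topology
  n <- nrow(idx)

  seed_row <- which(idx$traj == seed_frame[1] & idx$frame == seed_frame[2])
  if (length(seed_row) != 1L)
    stop("seed_frame is not among the strided frames")

  centers <- seed_row
  dmin <- ligand_rmsd_many(cube, cube[, , seed_row], top)
  assign <- rep(1L, n)
  while (max(dmin) > cutoff && length(centers) < n) {
    new_c <- which.max(dmin)
    centers <- c(centers, new_c)
    d_new <- ligand_rmsd_many(cube, cube[, , new_c], top)
    upd <- d_new < dmin   # strict: ties keep the earlier (lower) index
    assign[upd] <- length(centers)
    dmin[upd] <- d_new[upd]
  }

  structure(list(
    centers = idx[centers, , drop = FALSE],
    center_coords = cube[, , centers, drop = FALSE],
    assignments = data.frame(traj = idx$traj, frame = idx$frame,
                             cluster = assign, dist = dmin),
    cutoff = cutoff, stride = as.integer(stride), topology = top
  ), class = "ClusterModel")
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat(sprintf("ClusterModel: %d centers, cutoff %g A, stride %d, %d assigned frames (max dist %.3f A)\n",
              nrow(x$centers), x$cutoff, x$stride, nrow(x$assignments),
              max(x$assignments$dist)))
  invisible(x)
}

n_clusters <- function(model) nrow(model$centers)

#' Hybrid k-medoids refinement of a cluster model
#'
#' Stochastic medoid-swap refinement: in each pass, a random member of each
#' cluster is proposed as the replacement medoid and accepted when the
#' within-cluster sum of distances to the medoid does not increase; all
#' frames are then reassigned to their nearest medoid. The number of
#' clusters is fixed; the total within-cluster distance is non-increasing
#' across passes.
#'
#' @param model a `ClusterModel` from [kcenters()].
#' @param ens the [trajectory_ensemble()] the model was built from.
#' @param n_iter number of refinement passes (0 returns the model unchanged).
#' @param rng_seed integer seed for the medoid proposals.
#' @return a refined `ClusterModel` with an `objective` trace attached.
#' @export
kmedoids_refine <- function(model, ens, n_iter = 10L, rng_seed = 1L) {
  if (n_iter < 0L) stop("n_iter must be >= 0")
  if (n_iter == 0L) return(model)
  top <- ens$topology
  idx <- model$assignments[, c("traj", "frame")]
  cube <- gather_frames(ens, idx)
  K <- n_clusters(model)

  # medoid row positions within the strided frame set
  med <- match_rows(model$centers, idx)
  assign <- model$assignments$cluster
  dist <- model$assignments$dist
  objective <- numeric(n_iter)

  with_seed(rng_seed, {
    for (it in seq_len(n_iter)) {
      for (k in seq_len(K)) {
        members <- which(assign == k)
        cand <- if (length(members) == 1L) members else members[sample.int(length(members), 1L)]
        if (cand == med[k]) next
        d_cand <- ligand_rmsd_many(cube[, , members, drop = FALSE],
                                   cube[, , cand], top)
        if (sum(d_cand) <= sum(dist[members])) {
          med[k] <- cand
          dist[members] <- d_cand
        }
      }
      # reassign all frames to nearest medoids (ties -> lowest cluster index)
      D <- vapply(seq_len(K),
                  function(k) ligand_rmsd_many(cube, cube[, , med[k]], top),
                  numeric(dim(cube)[3]))
      assign <- max.col(-D, ties.method = "first")
      dist <- D[cbind(seq_len(nrow(D)), assign)]
      objective[it] <- sum(dist)
    }
  })

  out <- model
  out$centers <- idx[med, , drop = FALSE]
  out$center_coords <- cube[, , med, drop = FALSE]
  out$assignments <- data.frame(traj = idx$traj, frame = idx$frame,
                                cluster = assign, dist = dist)
  out$objective <- objective
  out
}

match_rows <- function(a, b) {
  match(paste(a$traj, a$frame), paste(b$traj, b$frame))
}

#' Assign ensemble frames to the nearest cluster centers
#'
#' Maps each (strided) frame to the center with the smallest
#' protein-aligned ligand RMSD; ties are broken toward the lowest cluster
#' index.
#'
#' @param ens a [trajectory_ensemble()] (must share the model's topology).
#' @param model a `ClusterModel`.
#' @param stride assign every `stride`-th frame (default 1: all frames).
#' @return data frame with columns `traj`, `frame`, `cluster`, `dist`.
#' @export
assign_frames <- function(ens, model, stride = 1L) {
  if (!identical(dim(ens$trajectories[[1]])[1], nrow(model$topology)))
    stop("ensemble topology does not match the cluster model")
  ft <- frame_table(ens)
  idx <- ft[seq(1L, nrow(ft), by = stride), , drop = FALSE]
  cube <- gather_frames(ens, idx)
  K <- n_clusters(model)
  D <- vapply(seq_len(K),
              function(k) ligand_rmsd_many(cube, model$center_coords[, , k],
                                           ens$topology),
              numeric(nrow(idx)))
  if (nrow(idx) == 1L) D <- matrix(D, nrow = 1L)
  cl <- max.col(-D, ties.method = "first")
  data.frame(traj = idx$traj, frame = idx$frame, cluster = cl,
             dist = D[cbind(seq_len(nrow(idx)), cl)])
}

#' Per-trajectory assignment sequences
#'
#' Splits a frame assignment table into one integer state sequence per
#' trajectory (ordered by frame), the discrete-trajectory form consumed by
#' the MSM estimators.
#'
#' @param assignments data frame from [assign_frames()] (or a
#'   `ClusterModel`'s `assignments`).
#' @return list of integer vectors of cluster indices.
#' @export
assignment_sequences <- function(assignments) {
  assignments <- assignments[order(assignments$traj, assignments$frame), ]
  unname(split(assignments$cluster, assignments$traj))
}

#' Write cluster assignments as CSV
#'
#' @param assignments assignment data frame.
#' @param path output CSV path (columns `traj`, `frame`, `cluster`).
#' @export
write_assignments <- function(assignments, path) {
  utils::write.csv(assignments[, c("traj", "frame", "cluster")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
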