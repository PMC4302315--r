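#' Superpose a frame onto a reference by its protein backbone
#'
#' Rigidly transforms (rotation + translation) all atoms of `frame` so that
#' its protein backbone atoms fit the reference frame's backbone in the
#' least-squares sense. The fit is the closed-form Kabsch solution with the
#' proper-rotation (reflection) correction, so the backbone residual is
#' minimal over all rigid transforms.
#'
#' @param frame `n_atoms x 3` coordinate matrix (Angstrom).
#' @param ref `n_atoms x 3` reference coordinate matrix.
#' @param top the [topology()]; only atoms flagged `backbone` enter the fit.
#' @return the transformed `n_atoms x 3` matrix.
#' @export
superpose_frame <- function(frame, ref, top) {
  check_frame(frame, top); check_frame(ref, top)
  bb <- backbone_idx(top)
  if (length(bb) < 3L) stop("superposition needs at least 3 backbone atoms")
  cpp_superpose(frame, ref, bb - 1L)
}

#' Protein-aligned ligand RMSD between two frames
#'
#' The pose metric of the whole protocol: `frame_a` is superposed onto
#' `frame_b` by a least-squares fit of the protein backbone atoms, and the
#' root-mean-square deviation is then taken over the ligand heavy atoms
#' only (positional atom correspondence, no ligand re-fitting). The metric
#' is directional by construction (alignment onto `frame_b`) but symmetric
#' in exact arithmetic for rigid fits.
#'
#' @param frame_a,frame_b `n_atoms x 3` coordinate matrices.
#' @param top the [topology()].
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(frame_a, frame_b, top) {
  check_frame(frame_a, top); check_frame(frame_b, top)
  cube <- array(frame_a, dim = c(nrow(frame_a), 3L, 1L))
  cpp_ligand_rmsd_many(cube, frame_b,
                       backbone_idx(top) - 1L, ligand_heavy_idx(top) - 1L)[1]
}

# vectorized form: RMSD of every slice of `frames` to `ref`
ligand_rmsd_many <- function(frames, ref, top) {
  as.numeric(cpp_ligand_rmsd_many(frames, ref,
                                  backbone_idx(top) - 1L,
                                  ligand_heavy_idx(top) - 1L))
}

check_frame <- function(frame, top) {
  if (!is.matrix(frame) || ncol(frame) != 3L)
    stop("a frame must be an n_atoms x 3 matrix")
  if (nrow(frame) != nrow(top))
    stop(sprintf("frame has %d atoms but topology has %d", nrow(frame), nrow(top)))
  invisible(frame)
}

#' Superpose every frame of an ensemble into a common protein frame
#'
#' Applies [superpose_frame()] to each frame against one reference frame,
#' which places all ligand coordinates in a shared protein-fixed frame as
#' required for grid occupancy mapping.
#'
#' @param ens a [trajectory_ensemble()].
#' @param ref reference frame matrix; default is the ensemble's first frame.
#' @return a new [trajectory_ensemble()] with transformed coordinates.
#' @export
superpose_ensemble <- function(ens, ref = NULL) {
  if (is.null(ref)) ref <- get_frame(ens, 1L, 1L)
  bb <- backbone_idx(ens$topology) - 1L
  coords <- lapply(ens$trajectories, function(tr) {
    out <- tr
    for (k in seq_len(dim(tr)[3]))
      out[, , k] <- cpp_superpose(tr[, , k], ref, bb)
    out
  })
  trajectory_ensemble(ens$topology, coords, ens$spacing, ens$ids)
}

#' Ligand pose in the protein-aligned frame
#'
#' @param coords `n_heavy x 3` matrix of ligand heavy-atom coordinates in the
#'   protein-aligned frame (Angstrom).
#' @param top the [topology()] the pose refers to.
#' @return an object of class `LigandPose`.
#' @export
ligand_pose <- function(coords, top) {
  validate_topology(top)
  if (!is.matrix(coords) || ncol(coords) != 3L ||
      nrow(coords) != length(ligand_heavy_idx(top)))
    stop("pose must be an n_heavy x 3 matrix matching the topology's ligand heavy atoms")
  structure(list(coords = coords, n_heavy = nrow(coords)), class = "LigandPose")
}

# extract the ligand heavy-atom pose from a full frame
pose_from_frame <- function(frame, top) {
  ligand_pose(frame[ligand_heavy_idx(top), , drop = FALSE], top)
}

# embed a pose into a full frame: reference frame with ligand replaced
frame_with_pose <- function(pose, ref_frame, top) {
  out <- ref_frame
  out[ligand_heavy_idx(top), ] <- pose$coords
  out
}

#' RMSD of a frame's ligand to a reference pose
#'
#' Superposes `frame` onto `ref_frame` (the protein frame in which `pose`
#' is expressed) by the protein backbone, then computes the heavy-atom RMSD
#' of the frame's ligand to the reference pose.
#'
#' @param frame `n_atoms x 3` coordinate matrix.
#' @param pose a [ligand_pose()].
#' @param ref_frame `n_atoms x 3` matrix defining the pose's protein frame.
#' @param top the [topology()].
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(frame, pose, ref_frame, top) {
  ligand_rmsd(frame, frame_with_pose(pose, ref_frame, top), top)
}
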