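#' Trajectory ensemble container
#'
#' A `TrajectoryEnsemble` holds any number of independent trajectories that
#' share one [topology()]. Each trajectory stores its frames as an
#' `n_atoms x 3 x n_frames` array of Cartesian coordinates in Angstrom, at a
#' uniform frame spacing in nanoseconds. Independent trajectories are the
#' unit of statistical independence downstream: transitions are never
#' counted across trajectory boundaries.
#'
#' @param top a [topology()] object shared by all trajectories.
#' @param coords list of coordinate arrays, one per trajectory; each either
#'   an `n_atoms x 3 x n_frames` array or an `n_atoms x 3` matrix (a single
#'   frame).
#' @param spacing frame spacing in ns (one value for the whole ensemble).
#' @param ids optional character vector of trajectory identifiers.
#'
#' @return an object of class `TrajectoryEnsemble` with elements
#'   `topology`, `trajectories` (list of arrays), `spacing`, `ids`.
#' @export
trajectory_ensemble <- function(top, coords, spacing, ids = NULL) {
  validate_topology(top)
  if (!is.list(coords) || length(coords) == 0L)
    stop("coords must be a non-empty list of coordinate arrays")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("frame spacing must be a single positive number (ns)")
  n <- nrow(top)
  coords <- lapply(coords, function(x) {
    if (is.matrix(x)) x <- array(x, dim = c(nrow(x), 3L, 1L))
    if (length(dim(x)) != 3L || dim(x)[2] != 3L)
      stop("each trajectory must be an n_atoms x 3 x n_frames array")
    if (dim(x)[1] != n)
      stop(sprintf("coordinate array has %d atoms but topology has %d", dim(x)[1], n))
    x
  })
  if (is.null(ids)) ids <- sprintf("traj%03d", seq_along(coords))
  ens <- structure(list(topology = top, trajectories = coords,
                        spacing = spacing, ids = as.character(ids)),
                   class = "TrajectoryEnsemble")
  ens
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  nf <- vapply(x$trajectories, function(t) dim(t)[3], integer(1))
  cat(sprintf("TrajectoryEnsemble: %d trajectories, %d frames total, %g ns spacing, %d atoms\n",
              length(x$trajectories), sum(nf), x$spacing, nrow(x$topology)))
  invisible(x)
}

n_frames <- function(ens) {
  sum(vapply(ens$trajectories, function(t) dim(t)[3], integer(1)))
}

# total simulated time in ns across all trajectories
aggregate_time_ns <- function(ens) n_frames(ens) * ens$spacing

#' Frame index table of an ensemble
#'
#' Enumerates all frames as (trajectory, frame) pairs in trajectory order;
#' this linear order is used for strides, cluster-center bookkeeping and
#' data prefixes in convergence analysis.
#'
#' @param ens a [trajectory_ensemble()].
#' @return data frame with columns `traj` and `frame` (both 1-based).
#' @export
frame_table <- function(ens) {
  nf <- vapply(ens$trajectories, function(t) dim(t)[3], integer(1))
  data.frame(traj = rep(seq_along(nf), nf),
             frame = unlist(lapply(nf, seq_len), use.names = FALSE))
}

# fetch one frame as an n_atoms x 3 matrix
get_frame <- function(ens, traj, frame) {
  ens$trajectories[[traj]][, , frame, drop = TRUE]
}

# stack a set of (traj, frame) rows into an n_atoms x 3 x n cube
gather_frames <- function(ens, idx) {
  n <- nrow(ens$topology)
  out <- array(0, dim = c(n, 3L, nrow(idx)))
  for (i in seq_len(nrow(idx)))
    out[, , i] <- ens$trajectories[[idx$traj[i]]][, , idx$frame[i]]
  out
}

#' Read an ensemble of trajectories from PDB or XYZ files
#'
#' One trajectory per input file, frames in file order. Multi-model PDB
#' files (`MODEL`/`ENDMDL` blocks) are read with \pkg{bio3d}; XYZ files with
#' the package's XYZ reader. Every frame must contain exactly the
#' topology's atom count, in topology order.
#'
#' @param paths character vector of trajectory file paths.
#' @param topology_path path to the plain-text topology file (see
#'   [read_topology()]), or a [topology()] object.
#' @param frame_spacing frame spacing in ns.
#' @return a [trajectory_ensemble()].
#' @export
read_ensemble <- function(paths, topology_path, frame_spacing) {
  top <- if (inherits(topology_path, "Topology")) topology_path else read_topology(topology_path)
  coords <- lapply(paths, function(p) read_frames(p, nrow(top)))
  trajectory_ensemble(top, coords, frame_spacing,
                      ids = tools::file_path_sans_ext(basename(paths)))
}

read_frames <- function(path, n_expect) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") read_xyz(path, n_expect)
  else if (ext %in% c("pdb", "ent")) read_pdb_frames(path, n_expect)
  else stop("unsupported trajectory format '", ext, "' for ", path)
}

read_pdb_frames <- function(path, n_expect) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE),
                  error = function(e) stop("failed to parse PDB file ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_atoms <- ncol(xyz) / 3L
  if (n_atoms == 0L) stop("empty trajectory file: ", path)
  if (n_atoms != n_expect)
    stop(sprintf("atom-count mismatch in %s: %d atoms per frame, topology has %d",
                 path, n_atoms, n_expect))
  nf <- nrow(xyz)
  out <- array(0, dim = c(n_expect, 3L, nf))
  for (k in seq_len(nf))
    out[, , k] <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
  out
}

#' Read / write XYZ trajectory files
#'
#' The XYZ format stores frames as repeated blocks: an atom-count line, a
#' comment line, then one `name x y z` line per atom. Coordinates are in
#' Angstrom.
#'
#' @param path file path.
#' @param n_expect expected atom count per frame (checked frame by frame).
#' @return `read_xyz` returns an `n_atoms x 3 x n_frames` array.
#' @export
read_xyz <- function(path, n_expect) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) == 0L) stop("empty trajectory file: ", path)
  frames <- list()
  i <- 1L
  fno <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    fno <- fno + 1L
    if (is.na(n)) stop(sprintf("malformed XYZ atom-count line at frame %d of %s", fno, path))
    if (n != n_expect)
      stop(sprintf("atom-count mismatch in %s at frame %d: %d atoms, topology has %d",
                   path, fno, n, n_expect))
    if (i + 1L + n > length(lines))
      stop(sprintf("truncated frame %d in %s", fno, path))
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    m <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (anyNA(m)) stop(sprintf("non-numeric coordinates at frame %d of %s", fno, path))
    frames[[fno]] <- m
    i <- i + 2L + n
  }
  out <- array(0, dim = c(n_expect, 3L, length(frames)))
  for (k in seq_along(frames)) out[, , k] <- frames[[k]]
  out
}

#' @rdname read_xyz
#' @param coords an `n_atoms x 3 x n_frames` array (or `n_atoms x 3` matrix).
#' @param names atom names written in the first column.
#' @param comment comment written on the second line of each frame block.
#' @export
write_xyz <- function(coords, path, names = NULL, comment = "") {
  if (is.matrix(coords)) coords <- array(coords, dim = c(nrow(coords), 3L, 1L))
  n <- dim(coords)[1]
  if (is.null(names)) names <- rep("X", n)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(dim(coords)[3])) {
    writeLines(c(as.character(n), comment), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", names,
                       coords[, 1, k], coords[, 2, k], coords[, 3, k]), con)
  }
  invisible(path)
}

#' Write frames as a multi-model PDB file
#'
#' Writes `MODEL`/`ENDMDL` blocks with one `ATOM` record per topology atom,
#' suitable for external viewers. Coordinates are printed at the PDB's
#' 1e-3 Angstrom precision.
#'
#' @param coords `n_atoms x 3 x n_frames` array or single-frame matrix.
#' @param top the [topology()] (atom names and roles become PDB fields).
#' @param path output path.
#' @export
write_frames_pdb <- function(coords, top, path) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(nrow(coords), 3L, 1L))
  stopifnot(dim(coords)[1] == nrow(top))
  resid <- ifelse(top$role == "protein", "PRO", "LIG")
  resno <- ifelse(top$role == "protein", 1L, 2L)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(dim(coords)[3])) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       seq_len(nrow(top)), substr(top$name, 1, 4), resid, resno,
                       coords[, 1, k], coords[, 2, k], coords[, 3, k]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
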