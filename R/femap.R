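#' Grid specification for volumetric maps
#'
#' A regular 3-D grid with half-open cubic cells `[lo, hi)` along each
#' axis. When no explicit box is given, grids are auto-fitted to the data
#' with one cell of padding on every side.
#'
#' @param origin numeric length-3, grid origin in Angstrom.
#' @param spacing cell edge in Angstrom (default 1.0).
#' @param dims integer length-3, number of cells per axis.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(origin, spacing = 1.0, dims) {
  stopifnot(length(origin) == 3L, length(dims) == 3L, spacing > 0, all(dims >= 1))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = as.integer(dims)), class = "grid_spec")
}

auto_grid <- function(positions, spacing = 1.0) {
  lo <- apply(positions, 2, min) - spacing
  hi <- apply(positions, 2, max) + spacing
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid_spec(lo, spacing, dims)
}

# linear (1-based) cell indices of points under the half-open convention
cell_index <- function(pos, spec) {
  ijk <- floor(sweep(pos, 2, spec$origin) / spec$spacing)
  if (any(ijk < 0) || any(sweep(ijk, 2, spec$dims - 1L) > 0))
    stop("positions fall outside the explicit grid; enlarge the box or use the auto grid")
  1L + ijk[, 1] + spec$dims[1] * (ijk[, 2] + spec$dims[2] * ijk[, 3])
}

#' Binary heavy-atom grid occupancy per Markov state
#'
#' For each state of the model, a cell gets occupancy 1 if any ligand heavy
#' atom of any frame assigned to that state falls inside the cell (half-open
#' cell intervals), else 0. Frames must already be superposed into a common
#' protein frame (see [superpose_ensemble()]); frames assigned to clusters
#' dropped by the ergodic trim are ignored.
#'
#' @param model a `TransitionModel`.
#' @param assignments full-resolution assignment data frame
#'   ([assign_frames()]), in the same (superposed) frame as `ens`.
#' @param ens the superposed [trajectory_ensemble()].
#' @param spec optional explicit [grid_spec()]; default auto-fits the
#'   ligand positions with one-cell padding.
#' @param spacing grid spacing in Angstrom used for the auto grid
#'   (default 1.0).
#' @param medoid_frames optional data frame (`traj`, `frame`) of one
#'   representative frame per original cluster; when given, occupancy uses
#'   only each state's medoid frame instead of all member frames.
#' @return list with `cells` (per-state integer vectors of occupied linear
#'   cell indices), `grid` (the [grid_spec()]), `K`.
#' @export
state_occupancy <- function(model, assignments, ens, spec = NULL,
                            spacing = 1.0, medoid_frames = NULL) {
  top <- ens$topology
  lig <- ligand_heavy_idx(top)
  keep <- assignments$cluster %in% model$mapping
  a <- assignments[keep, , drop = FALSE]
  state <- match(a$cluster, model$mapping)

  if (!is.null(medoid_frames)) {
    med_states <- match(seq_len(nrow(medoid_frames)), model$mapping)
    sel <- !is.na(med_states)
    a <- data.frame(traj = medoid_frames$traj[sel], frame = medoid_frames$frame[sel])
    state <- med_states[sel]
  }
  if (!setequal(unique(state), seq_len(model$K)))
    stop("inconsistent model: some states have zero assigned frames")

  # all ligand heavy-atom positions, frame by frame
  nh <- length(lig)
  pos <- matrix(0, nrow(a) * nh, 3L)
  for (i in seq_len(nrow(a)))
    pos[(i - 1L) * nh + seq_len(nh), ] <-
      ens$trajectories[[a$traj[i]]][lig, , a$frame[i]]
  if (is.null(spec)) spec <- auto_grid(pos, spacing)

  lin <- cell_index(pos, spec)
  st <- rep(state, each = nh)
  cells <- lapply(seq_len(model$K), function(j) sort(unique(lin[st == j])))
  list(cells = cells, grid = spec, K = model$K)
}

#' Map equilibrium state probabilities onto the grid
#'
#' Each cell's probability is the sum of the equilibrium populations of all
#' states whose binary occupancy covers it: `P(c) = sum_j o_jc * pi_j`.
#' Because occupancies are binary and `sum(pi) = 1`, every cell probability
#' lies in `[0, 1]`.
#'
#' @param occupancy output of [state_occupancy()].
#' @param model the `TransitionModel` providing `pi`.
#' @return an object of class `FreeEnergyGrid` with the probability array
#'   filled (`P`), energies unset.
#' @export
map_probabilities <- function(occupancy, model) {
  stopifnot(occupancy$K == length(model$pi))
  spec <- occupancy$grid
  P <- array(0, dim = spec$dims)
  for (j in seq_len(occupancy$K))
    P[occupancy$cells[[j]]] <- P[occupancy$cells[[j]]] + model$pi[j]
  structure(list(origin = spec$origin, spacing = spec$spacing,
                 dims = spec$dims, P = P, F = NULL,
                 mask = P > 0, temperature = NA_real_),
            class = "FreeEnergyGrid")
}

#' Convert cell probabilities to shifted free energies
#'
#' Occupied cells get `F(c) = -kB T log P(c)`, shifted so the minimum over
#' occupied cells is exactly zero; never-occupied cells stay masked (`NA`)
#' rather than carrying a value derived from `log(0)`. At 300 K,
#' `kB T = 0.59616` kcal/mol.
#'
#' @param grid a `FreeEnergyGrid` from [map_probabilities()].
#' @param temperature temperature in Kelvin (default 300).
#' @return the grid with the `F` array (kcal/mol) filled.
#' @export
to_free_energy <- function(grid, temperature = 300) {
  if (!any(grid$mask)) stop("no occupied cells; cannot map free energies")
  F <- array(NA_real_, dim = grid$dims)
  F[grid$mask] <- -KB_KCAL * temperature * log(grid$P[grid$mask])
  F[grid$mask] <- F[grid$mask] - min(F[grid$mask])
  grid$F <- F
  grid$temperature <- temperature
  grid
}

#' @export
print.FreeEnergyGrid <- function(x, ...) {
  cat(sprintf("FreeEnergyGrid: %d x %d x %d cells, %.2f A spacing, %d occupied%s\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, sum(x$mask),
              if (is.null(x$F)) "" else sprintf(", F range [0, %.3f] kcal/mol",
                                                max(x$F[x$mask]))))
  invisible(x)
}

#' Write / read an OpenDX volumetric file
#'
#' Standard OpenDX scalar-field text format (gridpositions,
#' gridconnections, data array; z-fastest row-major ordering), readable by
#' VMD/PyMOL for isosurface visualization. Masked (never-occupied) cells
#' are written as a sentinel value above every finite energy.
#'
#' @param grid a `FreeEnergyGrid` with energies filled ([to_free_energy()]).
#' @param path output `.dx` path.
#' @param sentinel value written for masked cells; default the maximum
#'   finite free energy plus 10 kcal/mol.
#' @export
write_opendx <- function(grid, path, sentinel = NULL) {
  if (is.null(grid$F)) stop("grid energies not filled; call to_free_energy() first")
  vals <- grid$F
  if (is.null(sentinel)) sentinel <- max(vals[grid$mask]) + 10
  vals[!grid$mask] <- sentinel
  d <- grid$dims
  # OpenDX data order: x slowest, z fastest
  flat <- as.vector(aperm(vals, c(3, 2, 1)))
  n <- length(flat)
  pad <- c(flat, rep(NA_real_, (3 - n %% 3) %% 3))
  rows <- matrix(pad, ncol = 3, byrow = TRUE)
  data_lines <- apply(rows, 1, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  header <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n))
  footer <- c("attribute \"dep\" string \"positions\"",
              "object \"free energy (kcal/mol)\" class field",
              "component \"positions\" value 1",
              "component \"connections\" value 2",
              "component \"data\" value 3")
  writeLines(c(header, data_lines, footer), path)
  invisible(path)
}

#' @rdname write_opendx
#' @return `read_opendx` returns a list with `origin`, `spacing` (length-3
#'   deltas), `dims`, and the `values` array in grid (x, y, z) order.
#' @export
read_opendx <- function(path) {
  lines <- readLines(path)
  gp <- grep("class gridpositions", lines, value = TRUE)[1]
  dims <- as.integer(strsplit(sub(".*counts ", "", gp), " ")[[1]])
  origin <- as.numeric(strsplit(sub("origin ", "", grep("^origin", lines, value = TRUE)[1]),
                                " +")[[1]])
  deltas <- vapply(grep("^delta", lines, value = TRUE)[1:3], function(l) {
    v <- as.numeric(strsplit(sub("delta ", "", l), " +")[[1]])
    v[v != 0][1]
  }, numeric(1))
  istart <- grep("data follows", lines)[1]
  iend <- grep("^(attribute|object \")", lines)
  iend <- min(iend[iend > istart], length(lines) + 1L) - 1L
  vals <- as.numeric(unlist(strsplit(trimws(lines[(istart + 1L):iend]), "[[:space:]]+")))
  vals <- vals[seq_len(prod(dims))]
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  list(origin = origin, spacing = unname(deltas), dims = dims, values = arr)
}

#' Full free-energy map from model + data in one call
#'
#' Superposes the ensemble into `ref_frame`'s protein frame, computes
#' binary state occupancies, maps equilibrium probabilities, and converts
#' to shifted free energies.
#'
#' @inheritParams state_occupancy
#' @inheritParams to_free_energy
#' @param ref_frame reference frame matrix defining the common protein
#'   frame (default the ensemble's first frame).
#' @return a `FreeEnergyGrid` with probabilities and energies filled.
#' @export
free_energy_map <- function(model, assignments, ens, ref_frame = NULL,
                            spec = NULL, spacing = 1.0, temperature = 300,
                            medoid_frames = NULL) {
  sup <- superpose_ensemble(ens, ref_frame)
  occ <- state_occupancy(model, assignments, sup, spec, spacing, medoid_frames)
  to_free_energy(map_probabilities(occ, model), temperature)
}

#' Dump a free-energy grid as CSV
#'
#' @param grid a `FreeEnergyGrid`.
#' @param path output CSV (`ix, iy, iz, P, F`; 0-based cell indices,
#'   occupied cells only).
#' @export
write_grid_csv <- function(grid, path) {
  occ <- which(grid$mask, arr.ind = TRUE)
  df <- data.frame(ix = occ[, 1] - 1L, iy = occ[, 2] - 1L, iz = occ[, 3] - 1L,
                   P = grid$P[grid$mask],
                   F = if (is.null(grid$F)) NA_real_ else grid$F[grid$mask])
  df <- df[order(df$ix, df$iy, df$iz), ]
  utils::write.csv(format(df, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
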