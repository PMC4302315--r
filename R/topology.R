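#' Atom topology for a protein-ligand system
#'
#' A `Topology` records, for every atom of the simulated system, its name,
#' whether it belongs to the protein or to the ligand, and the selection
#' flags the analysis relies on: protein *backbone* atoms define the rigid
#' superposition used to place every frame in a common protein frame, and
#' ligand *heavy* atoms define the RMSD metric used for clustering, bound
#' state definitions and convergence monitoring.
#'
#' @param name character vector of atom names.
#' @param role character vector, each entry `"protein"` or `"ligand"`.
#' @param backbone logical vector flagging protein backbone atoms. Ignored
#'   (forced `FALSE`) for ligand atoms.
#' @param heavy logical vector flagging ligand heavy atoms. Ignored (forced
#'   `FALSE`) for protein atoms.
#'
#' @return an object of class `Topology`: a data frame with columns
#'   `index` (0-based), `name`, `role`, `backbone`, `heavy`.
#' @export
topology <- function(name, role, backbone = NULL, heavy = NULL) {
  n <- length(name)
  stopifnot(length(role) == n)
  if (is.null(backbone)) backbone <- role == "protein"
  if (is.null(heavy)) heavy <- role == "ligand"
  stopifnot(length(backbone) == n, length(heavy) == n)
  if (!all(role %in% c("protein", "ligand")))
    stop("atom role must be 'protein' or 'ligand'")
  backbone <- backbone & role == "protein"
  heavy <- heavy & role == "ligand"
  top <- data.frame(index = seq_len(n) - 1L, name = as.character(name),
                    role = role, backbone = backbone, heavy = heavy,
                    stringsAsFactors = FALSE)
  class(top) <- c("Topology", "data.frame")
  validate_topology(top)
  top
}

validate_topology <- function(top) {
  if (!inherits(top, "Topology")) stop("not a Topology")
  if (!identical(top$index, seq_len(nrow(top)) - 1L))
    stop("topology atom indices must be unique and contiguous from 0")
  if (sum(top$backbone) < 3L)
    stop("topology needs at least 3 protein backbone atoms for a non-degenerate superposition")
  if (sum(top$heavy) < 1L)
    stop("topology needs at least 1 ligand heavy atom")
  invisible(top)
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms (%d protein, %d ligand); %d backbone, %d ligand heavy\n",
              nrow(x), sum(x$role == "protein"), sum(x$role == "ligand"),
              sum(x$backbone), sum(x$heavy)))
  invisible(x)
}

# 1-based row indices of the selections
backbone_idx <- function(top) which(top$backbone)
ligand_heavy_idx <- function(top) which(top$heavy)
protein_idx <- function(top) which(top$role == "protein")

#' Read / write a topology selection file
#'
#' Plain-text format, one atom per line with five whitespace-separated
#' columns: `index name role backbone heavy` where `role` is `protein` or
#' `ligand` and the flags are `0`/`1`. Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_topology` returns a [topology()] object.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("index", "name", "role", "backbone", "heavy"),
                           colClasses = c("integer", "character", "character",
                                          "integer", "integer"))
  ord <- order(tab$index)
  tab <- tab[ord, , drop = FALSE]
  topology(tab$name, tab$role, backbone = tab$backbone == 1L,
           heavy = tab$heavy == 1L)
}

#' @rdname read_topology
#' @param top a [topology()] object.
#' @export
write_topology <- function(top, path) {
  validate_topology(top)
  lines <- sprintf("%d %s %s %d %d", top$index, top$name, top$role,
                   as.integer(top$backbone), as.integer(top$heavy))
  writeLines(c("# index name role backbone heavy", lines), path)
  invisible(path)
}
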