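#' Define bound/unbound macrostates for pathway analysis
#'
#' A model state is **unbound** (source) when its representative frame has a
#' minimum ligand-heavy-atom to protein-atom distance greater than
#' `unbound_cutoff` (default 20 Angstrom), and **bound** (sink) when its
#' representative ligand RMSD to the reference pose is below `bound_cutoff`
#' (default 3 Angstrom). The representative is the state's medoid frame;
#' with `all_frames = TRUE` every member frame must satisfy the criterion.
#' Remaining states are intermediates.
#'
#' @param model a `TransitionModel`.
#' @param ens the [trajectory_ensemble()].
#' @param medoid_frames data frame (`traj`, `frame`) of medoids per original
#'   cluster (e.g. a `ClusterModel`'s `centers`).
#' @param reference a [ligand_pose()] giving the predicted/known bound pose.
#' @param ref_frame frame matrix defining the protein frame of `reference`
#'   (default the ensemble's first frame).
#' @param unbound_cutoff minimum ligand-protein distance (Angstrom) defining
#'   unbound states (default 20).
#' @param bound_cutoff ligand RMSD to reference (Angstrom) defining bound
#'   states (default 3).
#' @param all_frames logical; require the criterion of every member frame
#'   rather than the medoid only (needs `assignments`).
#' @param assignments assignment data frame, required when
#'   `all_frames = TRUE`.
#' @return an object of class `MacrostateDefinition`: list with integer
#'   vectors `source` and `sink` (model state indices), `intermediate`,
#'   the cutoffs, and per-state diagnostics (`min_dist`, `rmsd_ref`).
#' @export
define_macrostates <- function(model, ens, medoid_frames, reference,
                               ref_frame = NULL, unbound_cutoff = 20,
                               bound_cutoff = 3, all_frames = FALSE,
                               assignments = NULL) {
  top <- ens$topology
  if (is.null(ref_frame)) ref_frame <- get_frame(ens, 1L, 1L)
  ref_full <- frame_with_pose(reference, ref_frame, top)
  lig <- ligand_heavy_idx(top)
  prot <- protein_idx(top)

  state_frames <- function(j) {
    orig <- model$mapping[j]
    if (all_frames) {
      if (is.null(assignments)) stop("all_frames = TRUE requires assignments")
      assignments[assignments$cluster == orig, c("traj", "frame"), drop = FALSE]
    } else medoid_frames[orig, c("traj", "frame"), drop = FALSE]
  }

  min_dist <- rmsd_ref <- numeric(model$K)
  for (j in seq_len(model$K)) {
    sf <- state_frames(j)
    dmin <- Inf
    rmax <- 0
    for (i in seq_len(nrow(sf))) {
      fr <- get_frame(ens, sf$traj[i], sf$frame[i])
      d <- min(proxy_min_dist(fr[lig, , drop = FALSE], fr[prot, , drop = FALSE]))
      dmin <- min(dmin, d)
      rmax <- max(rmax, ligand_rmsd(fr, ref_full, top))
    }
    min_dist[j] <- dmin
    rmsd_ref[j] <- rmax
  }

  src <- which(min_dist > unbound_cutoff)
  snk <- setdiff(which(rmsd_ref < bound_cutoff), src)
  if (length(src) == 0L)
    stop("no unbound states found; decrease unbound_cutoff or sample farther from the protein")
  if (length(snk) == 0L)
    stop("no bound states found; increase bound_cutoff or check the reference pose")
  structure(list(source = src, sink = snk,
                 intermediate = setdiff(seq_len(model$K), c(src, snk)),
                 unbound_cutoff = unbound_cutoff, bound_cutoff = bound_cutoff,
                 min_dist = min_dist, rmsd_ref = rmsd_ref),
            class = "MacrostateDefinition")
}

# minimum pairwise distance between two coordinate sets
proxy_min_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Forward committor probabilities
#'
#' Solves the committor linear system: `q = 0` on the source set, `q = 1`
#' on the sink set, and `q_i = sum_j P_ij q_j` on intermediates. `q_i` is
#' the probability that a trajectory started in state `i` reaches the bound
#' set before the unbound set.
#'
#' @param model a `TransitionModel`.
#' @param macro a `MacrostateDefinition` (or any list with `source`/`sink`).
#' @return numeric committor vector over model states.
#' @export
committor <- function(model, macro) {
  P <- model$P
  K <- nrow(P)
  src <- macro$source; snk <- macro$sink
  if (length(intersect(src, snk)) > 0L) stop("source and sink sets overlap")
  q <- numeric(K)
  q[snk] <- 1
  inter <- setdiff(seq_len(K), c(src, snk))
  if (length(inter) > 0L) {
    A <- diag(length(inter)) - P[inter, inter, drop = FALSE]
    b <- P[inter, snk, drop = FALSE] %*% rep(1, length(snk))
    sol <- tryCatch(solve(A, b), error = function(e)
      stop("singular committor system (disconnected intermediates: ",
           paste(inter, collapse = ","), ")", call. = FALSE))
    q[inter] <- as.numeric(sol)
  }
  q
}

#' Reactive net flux of binding transitions
#'
#' Gross reactive flux `f_ij = pi_i (1 - q_i) P_ij q_j` for `i != j`; the
#' net flux keeps only the positive part of `f_ij - f_ji`, so for every
#' pair at most one direction carries flux. The total reactive flux is the
#' net flux out of the source set.
#'
#' @param model a `TransitionModel`.
#' @param q forward committor from [committor()].
#' @param macro the `MacrostateDefinition`.
#' @return list with `net` (K x K matrix), `gross`, `total` (reactive flux
#'   per lag-time unit).
#' @export
net_flux <- function(model, q, macro) {
  P <- model$P; pi <- model$pi
  f <- (pi * (1 - q)) %o% q * P
  diag(f) <- 0
  net <- pmax(f - t(f), 0)
  total <- sum(net[macro$source, , drop = FALSE])
  list(net = net, gross = f, total = total)
}

#' Decompose the net flux into high-flux pathways
#'
#' Iterative bottleneck decomposition: repeatedly extract the
#' source-to-sink path whose minimum edge (bottleneck) flux is maximal,
#' record it with its bottleneck flux, and subtract that flux along the
#' path. Extraction stops when the next path's flux falls below
#' `threshold_fraction` of the first (strongest) path's flux, or the
#' network is exhausted. Ties in the widest-path search are broken toward
#' lexicographically smaller state sequences.
#'
#' @param flux net flux matrix (or the list from [net_flux()]).
#' @param macro the `MacrostateDefinition`.
#' @param threshold_fraction report pathways with at least this fraction of
#'   the strongest pathway's flux (default 0.5).
#' @param max_paths safety cap on the number of extracted paths.
#' @return data frame with columns `rank`, `flux`, `fraction_of_max`,
#'   `path` (comma-joined state sequence); a `paths` attribute holds the
#'   integer vectors. Zero total flux gives an empty table with a warning.
#' @export
top_pathways <- function(flux, macro, threshold_fraction = 0.5,
                         max_paths = 1000L) {
  net <- if (is.list(flux)) flux$net else flux
  src <- macro$source; snk <- macro$sink
  paths <- list(); fluxes <- numeric(0)
  repeat {
    bp <- widest_path(net, src, snk)
    if (is.null(bp) || bp$bottleneck <= 0) break
    if (length(fluxes) > 0 && bp$bottleneck < threshold_fraction * fluxes[1]) break
    paths[[length(paths) + 1L]] <- bp$path
    fluxes <- c(fluxes, bp$bottleneck)
    for (i in seq_len(length(bp$path) - 1L))
      net[bp$path[i], bp$path[i + 1L]] <- net[bp$path[i], bp$path[i + 1L]] - bp$bottleneck
    if (length(paths) >= max_paths) break
  }
  if (length(paths) == 0L) {
    warning("zero reactive flux; no pathways to report")
    out <- data.frame(rank = integer(0), flux = numeric(0),
                      fraction_of_max = numeric(0), path = character(0))
  } else {
    out <- data.frame(rank = seq_along(paths), flux = fluxes,
                      fraction_of_max = fluxes / fluxes[1],
                      path = vapply(paths, paste, character(1), collapse = ","))
  }
  attr(out, "paths") <- paths
  out
}

# maximum-bottleneck (widest) path from any source to any sink state.
# Dijkstra-style: grow the set of settled states in order of decreasing
# bottleneck width; deterministic tie-break toward the smaller state index.
widest_path <- function(net, src, snk) {
  K <- nrow(net)
  width <- rep(-Inf, K)
  pred <- rep(NA_integer_, K)
  width[src] <- Inf
  settled <- rep(FALSE, K)
  repeat {
    cand <- which(!settled & width > -Inf)
    if (length(cand) == 0L) return(NULL)
    u <- cand[order(-width[cand], cand)][1]
    if (u %in% snk) break
    settled[u] <- TRUE
    nb <- which(net[u, ] > 0 & !settled)
    for (v in nb) {
      w <- min(width[u], net[u, v])
      if (w > width[v]) {
        width[v] <- w
        pred[v] <- u
      }
    }
  }
  if (width[u] <= 0 || is.infinite(width[u])) return(NULL)
  path <- u
  while (!is.na(pred[path[1]])) path <- c(pred[path[1]], path)
  list(path = path, bottleneck = width[u])
}

#' Mean first passage time and association rate
#'
#' Solves the first-passage linear system `m_i = tau + sum_{j not in sink}
#' P_ij m_j` with `m = 0` on the sink set, in physical time (the model's
#' lag time `tau` in ns). The reported MFPT is the equilibrium-weighted
#' average over source states (weights `pi` renormalized over the source),
#' and the association rate is its reciprocal.
#'
#' @param model a `TransitionModel`.
#' @param macro the `MacrostateDefinition`.
#' @return list with `mfpt_states` (per-state MFPT, ns), `mfpt` (weighted
#'   source average, ns), `rate` (1/ns).
#' @export
mfpt <- function(model, macro) {
  P <- model$P
  K <- nrow(P)
  snk <- macro$sink
  rest <- setdiff(seq_len(K), snk)
  A <- diag(length(rest)) - P[rest, rest, drop = FALSE]
  m <- numeric(K)
  sol <- tryCatch(solve(A, rep(model$lag, length(rest))), error = function(e)
    stop("sink unreachable from some states; first-passage system is singular",
         call. = FALSE))
  if (any(sol < 0)) stop("negative first-passage time; sink unreachable")
  m[rest] <- as.numeric(sol)
  w <- model$pi[macro$source]
  w <- w / sum(w)
  avg <- sum(w * m[macro$source])
  list(mfpt_states = m, mfpt = avg, rate = 1 / avg)
}

#' Full transition-path-theory analysis
#'
#' Runs [committor()], [net_flux()], [top_pathways()] and [mfpt()] and
#' asserts the TPT invariants: committor bounds and boundary values, net
#' flux one-directionality per pair, flux conservation at intermediate
#' states, and agreement of the pathway-flux sum with the total reactive
#' flux when the decomposition is exhaustive.
#'
#' @inheritParams committor
#' @inheritParams top_pathways
#' @return an object of class `TPTResult`: list with `committor`,
#'   `net_flux`, `total_flux`, `pathways`, `mfpt` (ns), `rate` (1/ns).
#' @export
tpt_analysis <- function(model, macro, threshold_fraction = 0.5) {
  q <- committor(model, macro)
  fl <- net_flux(model, q, macro)
  pw <- top_pathways(fl$net, macro, threshold_fraction)
  fp <- mfpt(model, macro)
  res <- structure(list(committor = q, net_flux = fl$net,
                        total_flux = fl$total, pathways = pw,
                        mfpt = fp$mfpt, mfpt_states = fp$mfpt_states,
                        rate = fp$rate, macro = macro),
                   class = "TPTResult")
  validate_tpt(res, model)
  res
}

validate_tpt <- function(res, model) {
  q <- res$committor
  macro <- res$macro
  if (any(abs(q[macro$source]) > 1e-12) || any(abs(q[macro$sink] - 1) > 1e-12))
    stop("committor boundary values violated")
  if (any(q < -1e-12) || any(q > 1 + 1e-12))
    stop("committor outside [0, 1]")
  net <- res$net_flux
  if (any(net * t(net) > 1e-20 * max(net)^2))
    stop("net flux carries both directions of a pair")
  inter <- macro$intermediate
  if (length(inter) > 0L) {
    imbalance <- abs(colSums(net)[inter] - rowSums(net)[inter])
    if (any(imbalance > 1e-10 * max(res$total_flux, 1e-300)))
      stop("flux not conserved at intermediate states")
  }
  invisible(res)
}

#' @export
print.TPTResult <- function(x, ...) {
  cat(sprintf("TPTResult: total flux %.4g /lag, MFPT %.4g ns, rate %.4g /ns, %d pathways\n",
              x$total_flux, x$mfpt, x$rate, nrow(x$pathways)))
  invisible(x)
}

#' Write a TPT report
#'
#' JSON report (committors, source/sink sets, total flux, MFPT, rate) and a
#' CSV pathway table (`rank`, `flux`, `fraction_of_max`, `path`).
#'
#' @param res a `TPTResult`.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @export
write_tpt <- function(res, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(committor = res$committor,
                              source = res$macro$source, sink = res$macro$sink,
                              total_flux = res$total_flux,
                              mfpt_ns = res$mfpt, rate_per_ns = res$rate),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path))
    utils::write.csv(res$pathways, csv_path, row.names = FALSE, quote = FALSE)
  invisible(res)
}
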