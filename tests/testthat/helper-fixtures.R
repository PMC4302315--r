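# Shared fixtures: small deterministic systems with geometry simple enough
# to compute every expected value by hand or brute force.

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal topology: 4 non-collinear backbone atoms + n_lig ligand heavy atoms
tiny_top <- function(n_lig = 1L) {
  topology(name = c("CA1", "CA2", "CA3", "CA4", sprintf("L%d", seq_len(n_lig))),
           role = c(rep("protein", 4), rep("ligand", n_lig)),
           backbone = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, n_lig)),
           heavy = c(rep(FALSE, 4), rep(TRUE, n_lig)))
}

tiny_protein <- function() {
  rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
}

# frame with the single-atom ligand at position p (length-3)
line_frame <- function(p) {
  rbind(tiny_protein(), matrix(p, 1, 3))
}

# ensemble whose 1-atom ligand sits at x-positions `xs` (list: one numeric
# vector per trajectory); protein fixed -> ligand RMSD == |x_a - x_b|
line_ensemble <- function(xs, spacing = 1) {
  top <- tiny_top(1L)
  coords <- lapply(xs, function(v) {
    arr <- array(0, dim = c(5L, 3L, length(v)))
    for (k in seq_along(v)) arr[, , k] <- line_frame(c(v[k], 0, 0))
    arr
  })
  trajectory_ensemble(top, coords, spacing)
}

# random rigid motion applied to an n x 3 coordinate matrix
random_rigid <- function(coords, seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t <- rnorm(3, 0, 5)
  sweep(coords %*% R, 2, t, "+")
}

# independent superposition + ligand RMSD oracle built on bio3d's rigid fit
bio3d_ligand_rmsd <- function(frame_a, frame_b, top) {
  bb <- which(top$backbone)
  lig <- which(top$heavy)
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(frame_b)),
                           mobile = as.vector(t(frame_a)),
                           fixed.inds = bio3d::atom2xyz(bb),
                           mobile.inds = bio3d::atom2xyz(bb))
  a_lig <- matrix(fitted[bio3d::atom2xyz(lig)], ncol = 3, byrow = TRUE)
  b_lig <- frame_b[lig, , drop = FALSE]
  sqrt(mean(rowSums((a_lig - b_lig)^2)))
}

# one shared toy-simulator run, computed on first use and reused everywhere
toy_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_toy_binding()
      cm_raw <- kcenters(sim$ensemble, cutoff = 3, stride = 8L)
      cm <- kmedoids_refine(cm_raw, sim$ensemble, n_iter = 3L, rng_seed = 1L)
      a <- assign_frames(sim$ensemble, cm)
      model <- build_msm(a, lag = 10, spacing = sim$ensemble$spacing)
      cache <<- list(sim = sim, cm_raw = cm_raw, cm = cm, assignments = a,
                     model = model)
    }
    cache
  }
})

# transition-model stub for estimator-independent TPT tests
model_stub <- function(P, pi = NULL, lag = 1) {
  if (is.null(pi)) {
    e <- eigen(t(P))
    v <- Re(e$vectors[, which.min(abs(e$values - 1))])
    pi <- abs(v) / sum(abs(v))
  }
  structure(list(P = P, pi = pi, eigenvalues = NULL, lag = lag,
                 mode = "naive", K = nrow(P), mapping = seq_len(nrow(P))),
            class = "TransitionModel")
}

macro_stub <- function(source, sink, K) {
  structure(list(source = source, sink = sink,
                 intermediate = setdiff(seq_len(K), c(source, sink)),
                 unbound_cutoff = 20, bound_cutoff = 3),
            class = "MacrostateDefinition")
}
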