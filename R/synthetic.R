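#' Exact sampling of a discrete-state Markov chain
#'
#' Draws state sequences from a given row-stochastic transition matrix, the
#' exact-oracle counterpart of the MSM estimators: statistics of the
#' sampled chains converge to the known matrix and its stationary
#' distribution.
#'
#' @param P row-stochastic transition matrix.
#' @param n_steps sequence length (number of states per trajectory).
#' @param n_traj number of independent trajectories.
#' @param rng_seed integer seed (reproducible sequences).
#' @param init optional initial distribution over states (default uniform),
#'   or a single fixed starting state index.
#' @param step_ns physical time per step in ns (recorded, not used).
#' @return list of integer state sequences (1-based).
#' @export
sample_chain <- function(P, n_steps, n_traj = 1L, rng_seed = 1L, init = NULL,
                         step_ns = 1) {
  K <- nrow(P)
  if (any(abs(rowSums(P) - 1) > 1e-12)) stop("transition matrix rows must sum to 1")
  if (any(P < 0)) stop("transition matrix entries must be >= 0")
  cum <- t(apply(P, 1, cumsum))
  init_cum <- if (is.null(init)) cumsum(rep(1 / K, K))
              else if (length(init) == 1L) cumsum(as.numeric(seq_len(K) == init))
              else cumsum(init / sum(init))
  with_seed(rng_seed, {
    lapply(seq_len(n_traj), function(t) {
      u <- stats::runif(n_steps)
      s <- integer(n_steps)
      s[1] <- findInterval(u[1], init_cum, left.open = TRUE) + 1L
      for (i in seq_len(n_steps - 1L))
        s[i + 1L] <- findInterval(u[i + 1L], cum[s[i], ], left.open = TRUE) + 1L
      s
    })
  })
}

#' Toy ligand-binding simulator specification
#'
#' A 3-D toy system with known thermodynamics for validating the whole
#' protocol: a static pseudo-protein (12 backbone atoms on a helix arc plus
#' a shell of surface atoms), a rigid 3-atom ligand whose centroid performs
#' a Metropolis random walk at temperature `T` in a potential that is a sum
#' of isotropic Gaussian wells — one deep "bound" well at the pocket and
#' shallower "nonspecific" wells — and flat elsewhere, inside a reflecting
#' cubic box. The Metropolis walk has the Boltzmann distribution of the
#' designed potential as its exact stationary law, so basin populations and
#' the top pose are known by construction.
#'
#' Default geometry: bound well of depth 4 kcal/mol at the pocket mouth
#' (6, 0, 0), two nonspecific wells of depth 1.5 kcal/mol, well widths
#' 2 Angstrom, box half-width 28 Angstrom (leaving an unbound shell more
#' than 20 Angstrom from every protein atom), 300 K. A broad confining
#' well (depth 4 kcal/mol, width 15 Angstrom) centered on the protein
#' plays the role of the limited unbound volume of a real solvated
#' simulation box: without it a free ligand spends nearly all its time in
#' the vast flat corners of the box, which no solvated MD system has.
#'
#' @param wells data frame with columns `x`, `y`, `z`, `depth` (kcal/mol),
#'   `width` (Angstrom); the first row is the bound well and must be the
#'   deepest.
#' @param confinement list with `depth` (kcal/mol) and `width` (Angstrom)
#'   of the broad origin-centered confining well; `NULL` disables it.
#' @param box_halfwidth reflecting-wall half-width in Angstrom.
#' @param temperature temperature in K.
#' @param step_sd Metropolis proposal standard deviation per axis (Angstrom).
#' @param n_steps Metropolis steps per trajectory.
#' @param n_traj number of independent trajectories.
#' @param stride store every `stride`-th step as a frame.
#' @param step_ns physical time assigned to one Metropolis step (ns).
#' @param rng_seed integer seed.
#' @return a `ToyBindingSpec` list (validated).
#' @export
toy_binding_spec <- function(wells = NULL,
                             confinement = list(depth = 4, width = 15),
                             box_halfwidth = 28,
                             temperature = 300, step_sd = 1.0,
                             n_steps = 20000L, n_traj = 20L, stride = 25L,
                             step_ns = 0.04, rng_seed = 1L) {
  if (is.null(wells))
    wells <- data.frame(x = c(6, -8, 0), y = c(0, 4, -9), z = c(0, 0, 5),
                        depth = c(4, 1.5, 1.5), width = c(2, 2, 2))
  spec <- structure(list(wells = wells, confinement = confinement,
                         box_halfwidth = box_halfwidth,
                         temperature = temperature, step_sd = step_sd,
                         n_steps = as.integer(n_steps), n_traj = as.integer(n_traj),
                         stride = as.integer(stride), step_ns = step_ns,
                         rng_seed = as.integer(rng_seed)),
                    class = "ToyBindingSpec")
  validate_toy_spec(spec)
  spec
}

validate_toy_spec <- function(spec) {
  w <- spec$wells
  if (nrow(w) >= 2L && any(w$depth[1] <= w$depth[-1]))
    stop("the bound well (first row) must be strictly deeper than all nonspecific wells")
  if (any(w$depth < 0) || any(w$width <= 0)) stop("well depths must be >= 0 and widths > 0")
  prot <- toy_protein_coords()
  ext <- max(sqrt(rowSums(prot$coords^2)))
  if (spec$box_halfwidth <= ext + 20)
    stop("box must contain a > 20 Angstrom unbound shell beyond the protein")
  if (any(abs(as.matrix(w[, c("x", "y", "z")])) >= spec$box_halfwidth))
    stop("all wells must lie inside the box")
  invisible(spec)
}

# static pseudo-protein: 12 backbone atoms on a helix arc + 8 shell atoms
toy_protein_coords <- function() {
  t <- seq(0, 3 * pi, length.out = 12)
  helix <- cbind(4 * cos(t), 4 * sin(t), seq(-4, 4, length.out = 12))
  phi <- seq(0, 2 * pi, length.out = 9)[-9]
  shell <- cbind(6 * cos(phi), 6 * sin(phi), rep(c(-2, 2), 4))
  list(coords = rbind(helix, shell),
       backbone = c(rep(TRUE, 12), rep(FALSE, 8)),
       names = c(sprintf("CA%d", 1:12), sprintf("S%d", 1:8)))
}

# rigid 3-atom ligand template, centroid at the origin
toy_ligand_template <- function() {
  L <- rbind(c(0.8, 0, 0), c(-0.4, 0.7, 0), c(-0.4, -0.7, 0))
  sweep(L, 2, colMeans(L))
}

#' Topology of the toy binding system
#'
#' @return a [topology()] with 20 protein atoms (12 backbone) and a 3-atom
#'   all-heavy ligand.
#' @export
toy_topology <- function() {
  prot <- toy_protein_coords()
  topology(name = c(prot$names, c("C1", "C2", "C3")),
           role = c(rep("protein", nrow(prot$coords)), rep("ligand", 3)),
           backbone = c(prot$backbone, rep(FALSE, 3)),
           heavy = c(rep(FALSE, nrow(prot$coords)), rep(TRUE, 3)))
}

# Gaussian-well potential at centroid positions (rows), kcal/mol
toy_potential <- function(pos, wells) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  U <- numeric(nrow(pos))
  for (k in seq_len(nrow(wells))) {
    d2 <- (pos[, 1] - wells$x[k])^2 + (pos[, 2] - wells$y[k])^2 +
      (pos[, 3] - wells$z[k])^2
    U <- U - wells$depth[k] * exp(-0.5 * d2 / wells$width[k]^2)
  }
  U
}

#' Run the toy binding simulator
#'
#' Metropolis random walk of the rigid ligand centroid in the designed
#' Gaussian-well potential with reflecting box walls. Trajectories start
#' from a mix of bound, near-bound and unbound positions (one third each,
#' emulating seeding from docked and translated poses). Returns the frames
#' in the standard ensemble data model together with a ground-truth record:
#' well definitions, the designed bound pose, analytic Boltzmann basin
#' weights (numerical quadrature of `exp(-U/kT)` over each basin), and
#' direct first-passage kinetics measured on the raw walk.
#'
#' @param spec a [toy_binding_spec()].
#' @return list with `ensemble` (a [trajectory_ensemble()], frame spacing
#'   `stride * step_ns` ns) and `ground_truth` (list: `wells`,
#'   `bound_pose`, `bound_center`, `basin_radius`, `basin_weights`,
#'   `basin_probability`, `entry_mfpt_ns`, `entry_rate_per_ns`,
#'   `n_entry_events`, `unbound_cutoff`, `bound_cutoff`).
#' @export
simulate_toy_binding <- function(spec = toy_binding_spec()) {
  validate_toy_spec(spec)
  top <- toy_topology()
  prot <- toy_protein_coords()$coords
  ligT <- toy_ligand_template()
  kT <- KB_KCAL * spec$temperature
  L <- spec$box_halfwidth
  # the confining well enters the potential as one more Gaussian well
  wells <- spec$wells
  if (!is.null(spec$confinement))
    wells <- rbind(wells, data.frame(x = 0, y = 0, z = 0,
                                     depth = spec$confinement$depth,
                                     width = spec$confinement$width))
  bound_center <- as.numeric(wells[1, c("x", "y", "z")])

  starts <- toy_start_positions(spec, prot)
  n_store <- spec$n_steps %/% spec$stride
  paths <- vector("list", spec$n_traj)

  with_seed(spec$rng_seed, {
    for (t in seq_len(spec$n_traj)) {
      pos <- starts[t, ]
      stored <- matrix(0, n_store, 3)
      prop_all <- matrix(stats::rnorm(3L * spec$n_steps, 0, spec$step_sd),
                         ncol = 3)
      u_all <- stats::runif(spec$n_steps)
      U_cur <- toy_potential(pos, wells)
      si <- 0L
      for (s in seq_len(spec$n_steps)) {
        prop <- reflect_box(pos + prop_all[s, ], L)
        U_new <- toy_potential(prop, wells)
        if (U_new <= U_cur || u_all[s] < exp(-(U_new - U_cur) / kT)) {
          pos <- prop
          U_cur <- U_new
        }
        if (s %% spec$stride == 0L) {
          si <- si + 1L
          stored[si, ] <- pos
        }
      }
      paths[[t]] <- stored
    }
  })

  n_atoms <- nrow(prot) + nrow(ligT)
  coords <- lapply(paths, function(p) {
    arr <- array(0, dim = c(n_atoms, 3L, nrow(p)))
    for (k in seq_len(nrow(p)))
      arr[, , k] <- rbind(prot, sweep(ligT, 2, p[k, ], "+"))
    arr
  })
  ens <- trajectory_ensemble(top, coords, spacing = spec$stride * spec$step_ns)

  basin_radius <- 2 * max(spec$wells$width)
  bw <- vapply(seq_len(nrow(spec$wells)), function(k)
    basin_weight(as.numeric(spec$wells[k, c("x", "y", "z")]), basin_radius,
                 wells, kT), numeric(1))
  box_weight <- total_box_weight(wells, kT, L)

  kin <- toy_entry_kinetics(paths, prot, bound_center,
                            spacing = spec$stride * spec$step_ns,
                            bound_cutoff = 3, unbound_cutoff = 20,
                            lig_template = ligT)

  gt <- list(wells = spec$wells,
             bound_center = bound_center,
             bound_pose = ligand_pose(sweep(ligT, 2, bound_center, "+"), top),
             basin_radius = basin_radius,
             basin_weights = bw,
             basin_probability = bw / box_weight,
             entry_mfpt_ns = kin$mfpt,
             entry_rate_per_ns = kin$rate,
             n_entry_events = kin$n_events,
             unbound_cutoff = 20, bound_cutoff = 3,
             temperature = spec$temperature)
  list(ensemble = ens, ground_truth = gt)
}

# reflect a point into the cube [-L, L]^3 (involutive mirror reflection)
reflect_box <- function(p, L) {
  for (i in 1:3) {
    x <- p[i]
    # fold into the period [-L, 3L) then mirror the upper half
    x <- ((x + L) %% (4 * L)) - L
    if (x > L) x <- 2 * L - x
    p[i] <- x
  }
  p
}

# start positions: 1/3 bound, 1/3 near-bound, 1/3 unbound (inside the seed RNG)
toy_start_positions <- function(spec, prot) {
  bound_center <- as.numeric(spec$wells[1, c("x", "y", "z")])
  L <- spec$box_halfwidth
  with_seed(spec$rng_seed + 1L, {
    starts <- matrix(0, spec$n_traj, 3)
    for (t in seq_len(spec$n_traj)) {
      kind <- (t - 1L) %% 3L
      if (kind == 0L) {
        starts[t, ] <- bound_center + stats::rnorm(3, 0, 0.5)
      } else if (kind == 1L) {
        starts[t, ] <- bound_center + stats::runif(3, -6, 6)
      } else {
        repeat {
          p <- stats::runif(3, -L, L)
          if (min(sqrt(colSums((t(prot) - p)^2))) > 22) break
        }
        starts[t, ] <- p
      }
    }
    starts
  })
}

# numerical quadrature of exp(-U/kT) over a spherical basin
basin_weight <- function(center, radius, wells, kT, h = 0.25) {
  g <- seq(-radius, radius, by = h)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  inside <- rowSums(pts^2) <= radius^2
  pts <- sweep(pts[inside, , drop = FALSE], 2, center, "+")
  sum(exp(-toy_potential(pts, wells) / kT)) * h^3
}

# quadrature of exp(-U/kT) over the whole box (coarse far from the wells)
total_box_weight <- function(wells, kT, L, h = 1) {
  g <- seq(-L + h / 2, L - h / 2, by = h)
  w <- 0
  for (z in g) {
    pts <- as.matrix(expand.grid(x = g, y = g))
    pts <- cbind(pts, z)
    w <- w + sum(exp(-toy_potential(pts, wells) / kT)) * h^3
  }
  w
}

# direct first-passage kinetics from the raw centroid paths: the hitting
# time of the bound region, recorded at every unbound frame and averaged
# over all of them (the trajectory-visitation-weighted unbound ensemble,
# matching the equilibrium-weighted source average of the MSM MFPT).
# Unbound frames with no later bound visit in their trajectory are censored
# and excluded; entry events are counted as unbound->bound first passages.
toy_entry_kinetics <- function(paths, prot, bound_center, spacing,
                               bound_cutoff, unbound_cutoff, lig_template) {
  hit <- numeric(0)
  n_events <- 0L
  for (p in paths) {
    # min distance of any ligand heavy atom to any protein atom, per frame
    dmin <- rep(Inf, nrow(p))
    for (a in seq_len(nrow(lig_template))) {
      atom <- sweep(p, 2, lig_template[a, ], "+")
      for (j in seq_len(nrow(prot))) {
        d <- sqrt(rowSums(sweep(atom, 2, prot[j, ])^2))
        dmin <- pmin(dmin, d)
      }
    }
    dcb <- sqrt(rowSums(sweep(p, 2, bound_center)^2))
    bound <- dcb < bound_cutoff
    unbound <- !bound & dmin > unbound_cutoff
    # backward sweep: frames until the next bound visit
    h <- rep(NA_real_, nrow(p))
    nxt <- NA_real_
    for (i in rev(seq_len(nrow(p)))) {
      if (bound[i]) nxt <- 0 else if (!is.na(nxt)) nxt <- nxt + 1
      h[i] <- nxt
    }
    hit <- c(hit, h[unbound & !is.na(h)] * spacing)
    # count unbound -> bound first-passage events
    t_un <- FALSE
    for (i in seq_len(nrow(p))) {
      if (unbound[i]) t_un <- TRUE
      if (bound[i] && t_un) { n_events <- n_events + 1L; t_un <- FALSE }
    }
  }
  if (length(hit) == 0L)
    list(mfpt = NA_real_, rate = NA_real_, n_events = n_events)
  else
    list(mfpt = mean(hit), rate = 1 / mean(hit), n_events = n_events)
}
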