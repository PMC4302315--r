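---
title: "Predicting ligand binding poses and pathways with Markov state models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ligand binding poses and pathways with Markov state models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

X-ray structures of protein–ligand complexes are often unavailable,
especially for low-affinity or transient binders. An alternative is to run
many independent binding simulations of the free ligand around the protein
and ask the statistics of those trajectories where the ligand prefers to
sit. `msmpose` implements the analysis half of that protocol: it turns an
ensemble of protein–ligand trajectories into a Markov state model (MSM),
ranks the ligand poses by their maximum-likelihood equilibrium population,
maps the model onto a 3-D free-energy grid, and extracts binding pathways
and association kinetics by transition path theory (TPT).

The MSM treats the ligand pose as a discrete-state Markov chain. States are
structural clusters obtained with k-centers clustering (plus hybrid
k-medoids refinement) under the metric of ligand heavy-atom RMSD after a
least-squares superposition of the protein backbone — so the metric sees
the ligand *relative to the protein*, not absolute motion. Transition
counts `C[i, j]` between states at a lag time `tau` give a row-stochastic
transition matrix `P` and its stationary distribution `pi`. Because the
underlying dynamics obey detailed balance, the default estimator is the
reversible maximum-likelihood one (a self-consistent fixed point on
symmetrized auxiliary counts); `pi` falls out of the reversible
parametrization directly. The state with the largest `pi` is the predicted
binding pose.

Model validity is checked through implied timescales
`t_i = -tau / log mu_i`: if the discrete dynamics are Markovian at lag
`tau`, the `t_i` do not depend on `tau`. The lag is chosen at the plateau
of those curves.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| cluster cutoff | 3 Å | k-centers covering radius in ligand RMSD |
| MSM lag `tau` | 10 ns | time between observations for counting |
| grid spacing | 1 Å | free-energy map cell edge |
| temperature | 300 K | used in `F = -kB T log P(c)`; `kB T = 0.59616` kcal/mol |
| reporting contour | 1 kcal/mol | isosurface for visual inspection |
| unbound cutoff | 20 Å | min ligand–protein distance defining the unbound macrostate |
| bound cutoff | 3 Å | ligand RMSD to the reference pose defining the bound macrostate |
| pathway fraction | 0.5 | report pathways carrying at least this fraction of the strongest pathway's flux |
| checkpoint interval | data-scale dependent | aggregate time between convergence checkpoints |
| convergence tolerance | 0.5 Å | declare convergence when the last two checkpoints agree this closely |

The cutoffs and the lag are the protocol's standard values for solvated
protein–ligand MD; on the bundled toy generator (below) the data-volume
parameters are scaled down (1 ns stored frame spacing, clustering stride 8
≈ 8 ns clustering interval, 2 µs checkpoints over 16 µs of aggregate data)
so every stage runs in seconds to minutes on one CPU. For production MD
with hundreds of µs of aggregate data, set `frame_spacing` to the
trajectory output spacing and use ~10 µs checkpoints.

## Free-energy mapping

Every frame is superposed into one protein frame. For each state `m_j`, a
grid cell `c_i` has binary occupancy 1 if any ligand heavy atom of any
frame assigned to `m_j` lies in the cell (half-open intervals `[lo, hi)`
per axis, so an atom exactly on a boundary belongs to the upper cell). The
cell probability is `P(c_i) = sum_j o_ij pi_j`, converted to
`F = -kB T log P(c_i)` and shifted so the occupied minimum is exactly 0.
Unoccupied cells are masked, never assigned a number derived from
`log(0)`; the OpenDX writer emits them as a sentinel above every finite
value so isosurfaces stay closed. Note the sign: high-probability cells
are free-energy *minima*; the map's global minimum should sit in the
binding site. Occupancy uses all frames of a state by default; a
medoid-only mode exists for comparison (`medoid_frames` argument) but
makes the map depend on a single conformation per state.

## Transition path theory

The bound (sink) and unbound (source) macrostates are defined from state
representatives: unbound means every ligand heavy atom is more than 20 Å
from every protein atom (no surface determination — any protein atom,
which is conservative), bound means ligand RMSD to the reference pose
under 3 Å. The representative is the state's medoid; an all-frames strict
mode is available. The forward committor solves
`q_i = sum_j P_ij q_j` with `q = 0/1` on source/sink; net fluxes
`max(0, f_ij - f_ji)` with `f_ij = pi_i (1 - q_i) P_ij q_j` decompose into
pathways by repeatedly extracting the widest (maximum-bottleneck) path and
subtracting its bottleneck flux — extraction stops below 50% of the first
path's flux. The association rate is reported as `1/MFPT` where MFPT is
the mean first-passage time to the bound set, averaged over source states
with weights `pi` renormalized on the source; the first-passage system is
solved in physical time (the lag in ns), and no concentration correction
is applied (converting to a second-order rate constant is out of scope).
Worth noting: an MFPT computed from an MSM cannot resolve processes faster
than the lag time, so the designed (or selected) lag should sit well below
the association timescale of interest.

## The synthetic generators and what they do (not) show

Two ground-truth generators make every stage testable without MD:

* `sample_chain()` draws exact trajectories from a known transition
  matrix, the oracle for the estimators (population recovery, implied
  timescales, counting).
* `simulate_toy_binding()` runs a Metropolis random walk of a rigid
  3-atom ligand's centroid around a static 20-atom pseudo-protein in a sum
  of Gaussian wells: one deep bound well (4 kcal/mol) at the pocket, two
  shallow nonspecific wells (1.5 kcal/mol), and a broad confining well
  (4 kcal/mol, 15 Å width) centered on the protein. The confinement plays
  the role of the limited unbound volume of a real solvated box — without
  it the walker spends most of its time in tens of thousands of Å³ of flat
  corner volume that no solvated MD system has, shattering the state space.
  The box half-width (28 Å) leaves a shell more than 20 Å from every
  protein atom so unbound macrostates exist. Metropolis dynamics were
  chosen over a literal Langevin integrator because their stationary law is
  *exactly* the Boltzmann distribution of the designed potential — no
  discretization bias — which makes quadrature of `exp(-U/kT)` an exact
  thermodynamic oracle. Trajectory starts mix bound, near-bound and
  unbound positions (one third each), emulating seeding from docked and
  grid-translated poses. One Metropolis step is declared 0.04 ns so that
  the association process (~25 ns measured directly) is slower than the
  10 ns lag; 20 trajectories × 20 000 steps stored every 25 steps give
  16 µs of aggregate data in ~16 000 frames.

What passing on this system shows: the estimators recover known
populations and spectra; clustering honors its covering guarantee; the
pipeline finds the designed pose, the free-energy minimum, and kinetics
within sampling error. What it does not show: robustness to protein
flexibility, ligand conformational change, metric degeneracies from
symmetric ligands, force-field error, or unconverged sampling — the real
failure modes of production MD. The convergence-series machinery is the
protocol's tool for the last of these, but only real data exercises it
meaningfully.

## Numerical choices

* Superposition is the closed-form Kabsch fit with the proper-rotation
  correction; collinear backbones are refused as degenerate. Identical
  point sets short-circuit to the identity transform.
* Ligand RMSD aligns frame a onto frame b and measures over ligand heavy
  atoms positionally (no symmetry correction — atom order is the
  correspondence). The metric is directional in floating point but
  symmetric in exact arithmetic; tests assert agreement to 1e-6 Å.
* k-centers seeds from the globally first frame; assignment ties break
  toward the lower cluster index; the hybrid k-medoids refinement accepts
  a proposed medoid swap when the within-cluster distance sum does not
  increase, so its objective is non-increasing (the covering radius
  guarantee belongs to the k-centers stage and may be traded away by
  refinement).
* Counting is sliding-window by default (maximal data use;
  independent-sample counting by flag). The reversible MLE iterates to a
  1e-10 max-element change, capped at 10 000 sweeps, and errors on
  non-convergence rather than returning a half-converged matrix.
* States outside the largest strongly connected component of the count
  graph are trimmed before estimation; the index map back to original
  clusters is kept on the model.
* In naive mode eigenvalues may be complex; implied timescales then use
  the modulus and are flagged `"complex"`. Non-positive eigenvalues are
  flagged `"undefined"` rather than producing NaN timescales.
* The committor, flux and MFPT systems are dense linear solves —
  appropriate for the few hundred states a 3 Å cutoff yields here.
* Pathway extraction breaks ties deterministically (smaller state index
  first), so repeated runs produce identical pathway tables.

## Design decisions that were genuinely open

* **Sign of the free-energy conversion.** Converting probabilities with a
  literal `+kB T log P` would make the most probable cells the highest in
  energy, contradicting the physical picture of a minimum-free-energy
  binding site; the package uses `F = -kB T log P` followed by the
  min-shift.
* **Rate from MFPT.** An "association rate" must have units of inverse
  time; the package reports `1/⟨MFPT⟩` with the π-weighted source
  average.
* **States are clusters.** No kinetic lumping (PCCA or similar) is applied
  between clustering and estimation; populations and rankings refer to the
  structural clusters themselves.
* **Both estimators are exposed** (`naive`, `reversible-mle`) since
  published equilibrium populations could come from either; the reversible
  one is the default because binding equilibria satisfy detailed balance.
* **Convergence declaration** uses an explicit rule (last two checkpoints
  within 0.5 Å) rather than visual inspection of the plot; the tolerance
  is configurable, and on the toy system the medoid identity jitters
  within the bound well by up to ~1 Å between checkpoints, so the plateau
  level (below the cluster cutoff) is the more meaningful signal.
* **Pose-seeding lattice spacing** defaults to 5 Å over a ±20 Å cube,
  yielding dozens of clash-free starting poses, in line with running on
  the order of fifty independent trajectories per round.

## A worked run

```{r, eval = FALSE}
library(msmpose)

sim <- simulate_toy_binding()           # ensemble + ground truth
ens <- sim$ensemble

cm <- kcenters(ens, cutoff = 3, stride = 8)
cm <- kmedoids_refine(cm, ens, n_iter = 3, rng_seed = 1)
a  <- assign_frames(ens, cm)

model <- build_msm(a, lag = 10, spacing = ens$spacing)
rank_states(model)[1:3, ]

grid <- free_energy_map(model, a, ens)
write_opendx(grid, "free_energy.dx")    # view the 1 kcal/mol contour in VMD

macro <- define_macrostates(model, ens, cm$centers,
                            sim$ground_truth$bound_pose)
tpt_analysis(model, macro)
```

The same protocol is scriptable per stage through `run_stage()` or the
`inst/cli/msmpose.R` command-line driver, with a single YAML configuration
controlling every parameter above.

## Known limitations

* Rigid-ligand, static-protein toy validation only; no torsional metric.
* Dense linear algebra limits models to a few thousand states.
* No Bayesian error bars on populations or rates; no reactive-trajectory
  extraction from the raw data.
* PDB/XYZ input only (text formats); no XTC/DCD readers.
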