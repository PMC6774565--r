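---
title: "Reduced-order superposition modeling of multi-cell ECM compaction"
author: "ecmsuper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order superposition modeling of multi-cell ECM compaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecmsuper)
```

## The scientific problem

Contractile cells embedded in a fibrous extracellular matrix (ECM) pull on
the fibers they adhere to, and when several cells act together the gel
compacts globally — far beyond what any single cell achieves. Simulating
this from first principles couples every membrane node of every cell to a
large cross-linked fiber network through discrete focal adhesions, which is
expensive and scales poorly with cell count. `ecmsuper` implements both
sides of this problem:

1. a **full nonlinear simulator** of overdamped cell–ECM mechanics
   (membrane meshes with cortical tension, fiber stretch + bending,
   focal-adhesion bonds, lamellipodial protrusion steered by a polarity
   vector), and
2. a **reduced-order pipeline** that linearizes the dynamics in an
   *augmented* state space (coordinates plus force variables), compresses
   it by PCA, identifies small linear latent systems from single-cell
   training runs, and predicts **multi-cell** behavior by superposing
   per-cell latent models through the shared latent ECM state.

## The mechanical model

Every node is inertialess: forces balance damping,
`D dx/dt = sum(F)`. Units are um, s, nN throughout.

**ECM** (`generate_network()`, `ecm_elastic_forces()`). Crosslink hub
points are sampled uniformly in the domain (cylinder or box); each hub is
joined to its `knn = 3` nearest hubs by a straight fiber subdivided into
segments, which guarantees a connected gel; additional crosslink springs
join unrelated nodes closer than `crosslink_radius`. A fraction of hubs is
cast onto the two clamped end planes so the gel is anchored like a gel
polymerized between plates. Mechanics per segment: linear axial springs
(`k_axial = 1` nN/um); per interior fiber node: a bending penalty on the
discrete curvature vector `x_{i-1} - 2 x_i + x_{i+1}` relative to its rest
value (`k_bend = 0.05`), a formulation whose gradient is exact, cheap, and
conserves total force. The as-generated geometry is the stress-free state.

**Cells** (`cell_mesh()`, `cortical_elastic_forces()`). The membrane is an
icosphere (subdivision 1: 42 nodes, 80 triangles, radius 7 um) with edge
springs (`k_edge = 1`) plus an isotropic cortical tension `gamma * area`
(`gamma = 0.3` nN/um) that always contracts the membrane; the equilibrium
between tension and edge springs sets a contracted area of roughly 60–70%
of rest, which is the traction driver for compaction.

**Focal adhesions** (`update_adhesions()`, `fa_forces()`). A membrane node
within `d_bind = 4` um of a free ECM node attaches with probability
`p_on = 0.5` per control step; a bond stretched beyond `d_break = 10` um
detaches. Each bond is a zero-rest-length spring of stiffness
`k_FA * n_int = 0.5 * 10` nN/um; forces come in equal-and-opposite pairs,
so the global adhesion force sum is exactly zero, and the sparse mapping
matrix `P_map` (blocks of `-I3`) routes cell adhesion forces onto their ECM
partners. At most one bond per membrane node; no ECM node is bound by two
cells. `d_bind`/`d_break` are desk-scale calibrations: with ~480 ECM nodes
in the 40 x 100 um cylinder, a 1-um capture shell would leave cells
essentially unattached, and weak bonds let cells crawl by rear-bond
rupture, whereas the regime modeled here is a *stationary* contracting
cell.

**Polarity and protrusion** (`update_polarity()`,
`lamellipodial_input()`, `max_stiffness_direction()`). A unit polarity
vector relaxes toward the local maximum-stiffness direction at rate
`kappa = 0.002`/s (slow compared with mechanical relaxation, so
protrusion-driven reorganization develops over tens of minutes). The
stiffness direction is estimated as the principal eigenvector of the local
fiber tension tensor `sum |T_s| u_s u_s^T` over segments within 15 um —
a documented, swappable stand-in for full stress-field sensing. Membrane
nodes inside the leading-edge cone (half-angle `pi/6`) get an outward force
`f_L = 0.3` nN. Protrusion requires adhesion-borne traction: a cell with
no bonds exerts no lamellipodial force (otherwise it would translate freely
under its own protrusion, which is unphysical).

**Integration** (`simulate_full()`). Explicit Euler, `dt = 0.1` s; with
`D_e = D_c = 10` nN.s/um all force/damping rates are below ~1/s, so the
scheme is stable with margin. The adhesion/polarity/input loop runs once
per sampling interval (1 s), after the position updates (order: forces,
positions, adhesions, polarity, inputs). Every stochastic element is under
one seed; trajectories are bit-reproducible.

## Dual-facet (augmented-state) linearization

The coordinate equations are *exactly linear* when the nonlinear force
terms are promoted to state variables:
`zeta_c = (x^c; F_CortElas; F_FA)` per cell (9 N_c entries) and
`zeta_e = (x^e; F_Elas)` for the ECM (6 N_e). Only the *force transitions*
`dF/dt` need fitted linear regressions — a dynamic rather than algebraic
linearization, which is why the approach can outperform a Taylor expansion:
the regression is trained on the trajectory distribution, not anchored at a
point. The scalar analogue is worked out in `toy_spring_system()` /
`toy_df_fit()`: for the hard spring `F = a x + b x^3` driving a damper, the
state facet `dx/dt = F/D` is exact and `dF/dt ~ S_x x + S_F F` is fitted;
for `b = 0` both facets coincide and the fit is exact.

## Reduction and identification

`build_latent_basis()` pools centered augmented samples over runs and
time, forms the two covariance matrices (or the thin SVD when samples are
scarce), and keeps the top `m_c` / `m_e` eigenvectors, with a
deterministic sign convention. Choices that matter:

* **Centering**: one global mean per entity over all runs/frames, stored
  with the basis. Because of centering, the exact latent dynamics of even
  a linear system are *affine*, so the regressions include intercepts
  (`a0`, `g0`) and the adhesion coupling carries a constant offset
  `d0 = V_x^e^T W P mu_FFA`.
* **Block scaling** (`block_scale`): optionally rescales coordinate and
  force blocks to unit pooled variance before PCA. Coordinates (um) and
  forces (nN) are incommensurate; unbalanced bases reconstruct forces
  poorly, and force-block reconstruction error integrates into spurious
  net drift of the cell centroid. The scaling is stored and inverted on
  reconstruction. In the default pipeline it is off: at desk scale the
  balanced basis trades too much geometric fidelity for force fidelity;
  both variants are exact in the linear-consistency limit.
* **Derivatives**: forward differences at the 1-s sampling interval — the
  exact adjoint of the explicit-Euler latent integrator, so an exactly
  linear training system is reproduced to numerical precision
  (central differences would leave an O(dt^2) scheme mismatch).
* **Switch frames**: sampling intervals during which the bond set changes
  are dropped from the regressions. The attach/detach event is handled
  *structurally* (the mapping matrices are re-assembled every step), so
  its derivative spike is not something `A` or `G` should absorb.

`estimate_parameters()` splits each latent equation into the analytically
known structural part — the projections of the exactly linear coordinate
facet through the damping constants, plus the matrix-free adhesion
injection — and a regression-only force-facet correction, fitted by ridge
least squares (`lambda` relative to the mean regressor variance; the
intercept and the known physics are never penalized). The couplings `D^k`
are assembled from known matrices (`assemble_Dk()`), never regressed, and
agree exactly with the matrix-free injection used in the simulator.
Eigenvalues of the identified `A`/`G` with real part above `-1e-4` are
clamped to that floor (eigenvectors kept): the physical system is
dissipative, but weakly excited latent modes pick up spuriously positive
rates at desk-scale data volumes; every clamp is reported and the raw
spectral abscissae are stored.

`simulate_latent()` closes the loop: per 1-s step it reconstructs
geometry through the basis, updates adhesions on the reconstructed
coordinates, re-forms the mapping matrices, runs the polarity/input loop
on the reconstructed tension field, and advances
`dz_c,k/dt = A z_c,k + B u_k + C z_e + a0` and
`dz_e/dt = G z_e + sum_k inj_k + g0`. Cells interact only through `z_e` —
adding a cell adds one copy of the same single-cell-trained model and one
injection term, which is the superposition property.

## Baselines

`simulate_taylor()` freezes the elastic/cortical force fields at their
first-order Taylor expansion about the initial configuration (adhesion and
protrusion forces stay exact — the adhesion force is already linear given
the bond set). `tpwl_model()` / `simulate_tpwl()` build a trajectory
piecewise-linear surrogate: ~kappa points are picked by greedy arc-length
sampling along the training trajectories (pooled across runs), each with
its own affine model, blended by normalized Gaussian kernel weights in
state distance (bandwidth: median spacing of the selected points; only the
top 6 weights are evaluated). With a single point TPWL reduces exactly to
the Taylor baseline. The blended Jacobians are transiently stiffer than
either endpoint model, so the TPWL baseline integrates at `dt = 0.02` s
(the comparison is recorded at the same 1-s sampling).

## Desk-scale study protocol

The full-scale study conditions (N_e ~ 2000, N_c ~ 200, 1-h runs repeated
~10 times, 24–120 h of computation per run) are not reproducible on a
desktop; all experiments here run a reduced mesh: N_e ~ 480 (110 fibers of
4 segments), N_c = 42, in the same 40 x 100 um cylinder with clamped end
planes. The training protocol is 6 single-cell runs of 3000 s (1-s
sampling) at coverage-checked random cell locations — training covers the
full prediction horizon of the compaction experiment; `lambda` is selected
by re-simulating one held-out run. The single-cell model comparison is
evaluated over a 600-s horizon — the gel-contraction transient, and the
first comparison time point reported for the compaction study (t = 10
min). Beyond that window, rollouts of *every* model family (including the
full-order baselines) are increasingly dominated by the stochastic
attach/detach decisions and the polarity feedback, which amplify tiny
state differences into diverging bond histories; errors then approach the
frozen-state null error and no longer measure mechanical model fidelity.
The two-cell compaction analysis, whose read-outs are bulk volumes rather
than node-wise errors, runs to t = 50 min.

## What the generator emulates — and what it does not

The synthetic fixtures (`make_fixture()`) reproduce the study scenarios:
a single cell in the cylinder, two cells 30/50/100 um apart on the axis,
and a half-scale rectangular gel with a 5-cell cluster plus an isolated
cell. The generator emulates: stress-free random fibrous geometry with
clamped ends, O(10–40) adhesions per cell, minutes-scale contraction, and
slice-wise compaction strongest around and between cells. It does not
emulate: fiber plasticity or rupture, matrix degradation, nonlinear
(catch/slip) bond kinetics, strain-stiffening continuum response, or the
full-scale network homogeneity — so passing tests here demonstrate the
method's internal consistency and its qualitative agreement with the
study regime at reduced scale, not quantitative agreement with real
collagen-gel experiments.

## Numerical choices and degenerate inputs

Collapsed segments, zero-area triangles, non-finite coordinates, empty
sensing neighborhoods and rank-deficient regressions all raise immediately
with informative messages. Convex-hull volumes (compaction metric) use a
direct facet-enumeration hull with plane deduplication — adequate and
dependency-free at per-slice point counts (~50); an alpha-shape was
rejected because its radius parameter is fragile at desk-scale densities
(a documented limitation for strongly concave deformation). Slice
membership is material (by initial axial position), which keeps V(t)/V(0)
well defined under large deformation. PCA ties are broken by making the
largest-magnitude eigenvector entry positive; the maximum-stiffness
eigenvector sign points toward the higher-tension half-space with a
lexicographic tie-break.

## Known limitations

* **Spatial generalization of the basis is the binding constraint for
  multi-cell prediction at desk scale.** On an N_e ~ 500 network each
  cell's deformation field is idiosyncratic to its local fiber geometry;
  projecting even the *true* two-cell compacted state onto the
  single-cell-trained ECM basis recovers only about half of the total
  volume shrinkage, regardless of how many single-cell runs feed the
  covariance. The latent superposition therefore under-predicts two-cell
  compaction here, while the single-cell benchmark (whose states the basis
  spans) is reproduced below 10% of the cell radius. Denser, more
  homogeneous networks make single-cell deformation fields transferable
  between locations, which is what the reduction relies on.
* The latent model is time-invariant while the true dynamics are
  bond-set-dependent; only the adhesion injection tracks topology changes,
  so long-horizon node-wise accuracy degrades once bond histories diverge.
* The identified models are stabilized by spectral clamping when needed —
  a repair, flagged on every occurrence, not a guarantee of closed-loop
  stability of the coupled cell–ECM system.
* Desk-scale networks are strongly heterogeneous; quantities averaged over
  slices or cells are far more reproducible across seeds than node-wise
  errors.
* The ridge/latent-dimension trade-off is data-volume limited: past
  m ~ 50 per entity the extra modes are weakly excited and can hurt
  rollouts even after stabilization.
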