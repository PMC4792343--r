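---
title: "Polyline cell mechanics: model, parameters and numerical choices"
author: "polycell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polyline cell mechanics: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycell)
```

## The model

`polycell` simulates planar aggregates of cells whose mechanics are reduced
to two ingredients.  First, every piece of cell boundary carries a *net
interfacial tension* $\gamma$ — the combined effect of cortical
contraction and cell–cell adhesion — which acts tangentially and tends to
shorten the boundary.  Tensions depend only on the *interface class*: the
unordered pair of region types the boundary separates (two cell types, or
a cell type and the surrounding medium).  Second, the cytoplasm is
passive and viscous: each cell grounds its boundary nodes through pairs of
orthogonal dashpots, so motion is overdamped and inertia plays no role.

Cell edges are represented as **polylines**: chains of straight rod
elements joined by intermediate nodes.  All rods of one edge carry the same
tension.  Because intracellular pressures differ between neighbouring
cells, edges bow outward from the high-pressure side until the transverse
components of the rod tensions balance the pressure load, like a
discretized membrane; at equilibrium an edge approximates a circular arc
obeying the Young–Laplace relation $\kappa = \Delta p / \gamma$.  The
classical straight-edge (**monoline**) vertex model is the special case in
which cell–cell edges are single rods.  A straight edge cannot bow, so it
behaves like a beam: the pressure difference across it is carried to its
end junctions as an equivalent transverse shear $V = \tfrac12\,\Delta p\,L$
(`equivalent_shear()`), which perturbs the junction force balance away from
the Young angles and can arrest motions — this is the mechanical origin of
every monoline/polyline difference this package measures.  Cell–medium
boundaries remain segmented in both modes (they are routinely treated as
curved in straight-edge models, and a two-cell aggregate would otherwise
have no area); "monoline" therefore constrains exactly the cell–cell
edges.

Each time step solves the saddle-point system

$$
\begin{pmatrix} \tfrac1{\Delta t}\mathbf C & \mathbf G^\top \\
\mathbf G & 0 \end{pmatrix}
\begin{pmatrix}\Delta\mathbf u \\ \boldsymbol\lambda\end{pmatrix} =
\begin{pmatrix}\mathbf f \\ \mathbf r\end{pmatrix}
$$

where $\mathbf f$ assembles the rod tensions into nodal forces (exactly
$-\nabla$ of the boundary energy $\sum_e \gamma_e L_e$), $\mathbf C$ is the
diagonal dashpot matrix, $\mathbf G$ holds the per-cell shoelace area
gradients and $\mathbf r = A_0 - A$ restores each cell toward its target
area.  An updated-Lagrangian scheme re-evaluates geometry, $\mathbf f$ and
$\mathbf C$ every step.  The negated multipliers are the cell pressures
(medium $\equiv 0$); the sign is fixed so a contracting isolated cell has
positive internal pressure, which the test suite pins against the
closed-form pressure-vessel value $p = \gamma / R$.

The dashpot coefficient of cell $c$ at each of its nodes is
$k_c = \mu_c A_c / n_{\mathrm{eff}}(c)$ with
$n_{\mathrm{eff}} = \#\text{junction nodes} + \tfrac12\,\#\text{intermediate
nodes}$: intermediate nodes carry half weight, so the total drag of a cell
is insensitive to how finely its edges are segmented.  We take the product
form $\mu A / n_{\mathrm{eff}}$ as the coefficient; any overall constant
only rescales time.  Because the dashpots are grounded and isotropic,
$\mathbf C$ is diagonal and positive definite, rigid-body modes are damped
without artificial anchoring, and the solve reduces to a small Schur
complement on the cell-count–sized constraint block.

## Topological events

* **T1 neighbour exchange** (`apply_t1_exchanges()`): a junction–junction
  edge shorter than $\delta$ = `t1_threshold_frac` (default 2.5% of the
  mean cell diameter $D$) is eliminated and replaced by a new edge joining
  the two formerly separated regions, perpendicular to the old edge at its
  midpoint, with length `post_t1_length_frac` (default 3.75% of $D$, long
  enough that the exchange cannot immediately reverse).  The new tension is
  looked up by the new interface class.  Candidates are processed shortest
  first; exchanges that would produce a two-edged cell are skipped and
  logged.  Short edges bordering the medium are exchanged by the same
  rewiring whenever their two flanking regions differ — topologically this
  is the junction merge followed by a quad-junction split across the
  flanking diagonal.  When both flanking regions are the same cell (the
  pinch-off configuration at the end of engulfment) no valid exchange
  exists; the event is skipped and a length floor (half of $\delta$)
  keeps the shrinking edge numerically alive.  Full topological closure of
  an inclusion (two separate boundary loops) is a known limitation; runs
  simply hold the near-closed state.
* **Embargo timer**: a freshly created edge is protected from re-exchange
  for `embargo_steps` steps.  The duration is not critical; 20 steps is the
  default where it is enabled.  It matters wherever an exchange creates a
  high-tension edge that would immediately shorten and flip back — the
  tissue-engulfment, invasion and checkerboard defaults enable it (without
  it the invasion scenario thrashes with thousands of reversing
  exchanges), annealing and sorting leave it off.
* **Refinement / coarsening** (`refine_and_coarsen()`): segments longer
  than `seg_max_frac` (default 25% of $D$) are bisected, repeatedly, with a
  new intermediate node at each midpoint; segments shorter than
  `seg_min_frac` (default 2.5% of $D$) collapse — two intermediate ends
  merge to a fresh node at the segment midpoint, an intermediate end merges
  into its junction (which keeps its position), and a short
  junction–junction edge is left to the T1 rule.  The default band yields
  roughly 2–3 intermediate nodes per edge for near-isotropic cells, with
  longer (hence more curved) edges automatically receiving more.
* **Quad junctions and rosettes** (`split_higher_order_junction()`): nodes
  with four or more incident edges are replaced by chains of closely spaced
  triple junctions (connector length `seg_min_frac`·$D$), preserving the
  cyclic edge order.  Connector edges are flagged and excluded from both
  T1 scans (until they have grown past the post-exchange length) and
  junction-angle scoring, since an artificial split pair does not carry a
  physical contact angle.
* **Ordering within a step**: coarsen → T1 → refine → viscous solve.  T1
  is defined on intermediate-free short edges, so coarsening must run
  first; refining last hands the solver a compliant mesh.

## Initial conditions

`voronoi_tissue()` builds a finite isolated aggregate scaled so the mean
cell diameter $D \approx 1$ (the unit of length).  With
`size_variation = 0` generators are sampled uniformly in a disc and
Lloyd-relaxed, giving a well-annealed tessellation.  With
`size_variation` $= \sigma > 0$ cell sizes are varied *intentionally*:
target areas are drawn from a lognormal with log-sd $\sigma$ and realized
by a Laguerre (power) tessellation of dart-thrown, non-overlapping disc
centres — the classical construction for polydisperse foams.  The default
for annealing, $\sigma = 0.5$ (area coefficient of variation around
0.4–0.6), produces the strong intracellular pressure differences that bulge
polyline edges under uniform tension.  Cell polygons are computed by
half-plane (radical-axis) clipping, which is $O(n^2)$ and entirely adequate
at the few hundred cells these studies use; degenerate vertices are
normalized through the rosette splitter.  Target areas are set to the
initial polygon areas, and the whole construction is a pure function of the
seed.

## Scenarios

`build_scenario()` encodes six interaction studies.  The regimes are
defined by tension *inequalities*; since no published magnitudes exist for
most of them, the defaults satisfy each inequality with a comfortable
margin and are fully overridable (construction fails, naming the
inequality, if an override breaks the regime):

| scenario | cells | defining condition | default tensions |
|---|---|---|---|
| annealing | 50, one type, $\sigma=0.5$ | all tensions equal | $\gamma = 1$ |
| cell_engulfment | 2 | $\gamma_{gm}+\gamma_{gy} < \gamma_{ym}$ | 1, 1, 3 |
| tissue_engulfment | 30, two blocks | same, plus $\gamma_{gg} > \gamma_{gy}$ | $\gamma_{gg}=1.6$, $\gamma_{gy}=0.8$, $\gamma_{ym}=3$, $\gamma_{gm}=0.6$, $\gamma_{yy}=1$ |
| sorting | 200, random 50/50 | $\gamma_{gy} > (\gamma_{gg}+\gamma_{yy})/2$ | 1, 1, 1.6; media 1.2 / 2.2 |
| invasion | 6 + 40 | $\gamma_{gy} < (\gamma_{gg}+\gamma_{yy})/2$, $\gamma_{gg}$ high | 1.6, 0.8, 0.7; media 1.2 |
| checkerboard | 60, random 50/50 | $\gamma_{gy} \ll \gamma_{gg}, \gamma_{yy}$ | 1, 1, 0.2; media 1.5 |

Two-type layouts follow the published imagery generically: engulfment and
invasion cut blocks from one tessellation by centroid abscissa; sorting and
checkerboard assign types randomly under the run seed.  `run_pair()` runs
the identical initial mesh and seed in both modes, so every difference
between the trajectories is attributable to the straight-edge constraint.

## Measurements

* `fit_circular_arc()` fits a circle to an edge's node chain by Taubin's
  algebraic method (a brute-force geometric least-squares oracle backs it
  in the tests); near-straight chains report infinite radius.  Curvature is
  signed positive when the centre lies left of the chain, making
  $\kappa = (p_{\mathrm{left}} - p_{\mathrm{right}})/\gamma$ the
  Young–Laplace convention.
* `young_angles()` gives the unique force-balance angles of three tensions
  (error if the triangle inequality fails, since no equilibrium junction
  exists).  `junction_angle_errors()` scores each 3-valent junction by the
  RMS difference (in degrees) between observed and Young angles, pairing
  angles by interface identity so no matching ambiguity arises.  Observed
  directions come from arc tangents (`arc_tangent`) or the first polyline
  segment (`nearest_segment`, the only meaningful choice for monoline
  edges).
* `aggregate_metrics()` produces the time series used for model
  comparison: median/mean junction error, mean $|\kappa|$ of an interface
  class normalized by the equal-area-circle radius of the average cell,
  class boundary length normalized to its initial value, and mean (or
  horizontal) centroid displacement of tracked cells in cell diameters,
  against dimensionless time $t^* = t\,\bar\gamma /(\mu D)$.  The
  time-scale choice only stretches the abscissa; we use the mean initial
  tension as $\bar\gamma$.
* `compare_trajectories()` condenses a matched pair into one discrepancy
  percentage per quantity ($|a-b| / \overline{ab} \times 100$,
  trapezoid-averaged over the common dimensionless-time range), except
  curvature, which is compared at the terminal configurations only because
  straight edges carry identically zero curvature.

## Numerical choices

* **Time step**: explicit geometry updates of an overdamped rod network
  are stable for $\Delta t < k L / \gamma$ (node dashpot $k$, segment
  length $L$).  By default the step is chosen adaptively every iteration as
  half that bound over all segments; the safety factor is not critical and
  terminal statistics are insensitive to it.  A deterministic clamp additionally caps any single nodal
  move at 40% of the minimum segment length during fast transients.
* **Constraint treatment**: area gradients are evaluated at the step
  start (explicit geometry, implicit constraint) and the right-hand side
  restores the full residual $A_0 - A$ each step, so area drift is
  self-correcting and stays at rounding level (the suite bounds it at
  $<0.1\%$ over 1000 steps of the sorting scenario).
* **Stationarity**: a run is terminal when the largest nodal move per step
  stays below $10^{-5} D$ for 50 consecutive steps ("meaningful movement
  ceases" is not otherwise quantified).
* **Determinism**: all randomness flows from the run seed through an
  isolated RNG scope; identical seeds give byte-identical trajectories.
  T1 candidates are processed shortest first, and a candidate touching a
  neighbourhood already modified this step is deferred one step.
* **Problem sizes**: the shipped checks use 50-cell aggregates, three
  seeds, runs capped at 7000–15000 steps (stationarity usually arrives
  first), a 50-cell sorting run for the conservation check and the 2-cell
  and 46-cell engulfment/invasion studies.  The segments-per-edge study
  re-tunes the relaxed polyline state to ~3 and ~10 segments per edge and
  relaxes again, which reaches the same terminal state as running at that
  resolution from the start at a fraction of the cost (the same
  continuation logic the invasion study applies to monoline states).

## What the generator does and does not emulate

The synthetic tessellations reproduce the *geometric* starting conditions
of aggregate experiments — polygonal cells, size polydispersity, a smooth
free surface — and the dynamics reproduce tension-driven relaxation,
neighbour exchange and spreading.  They do not include protrusive
motility, chemotaxis, cell division or death, elastic (storage) response
of the cytoplasm, three-dimensional effects, or biological noise in the
tensions.  Passing checks therefore demonstrate the mechanical
consequences of edge representation under controlled tension fields, not
agreement with any particular experimental tissue.

## Known limitations

* Complete engulfment is held at a near-closed pinch rather than resolved
  into a true inclusion (separate boundary loops); the medium-exposed
  boundary of the engulfed cell reaches a fraction of a percent of its
  initial length and stays there.
* The monoline annealing angle errors scale with the size dispersion of
  the initial tessellation, for which no published value exists.  Under
  the default $\sigma = 0.5$ the interior-junction RMS errors average
  10–12°; stronger dispersion raises them.  The polyline arc-tangent
  errors are insensitive to this choice (sub-degree in all conditions
  tried).
* Rosettes are never treated directly — only as split chains of triple
  junctions — and junctions belonging to such chains are excluded from
  angle scoring.
* With matched seeds the two modes can bifurcate topologically (different
  T1 histories), which is physical but means trajectory comparisons are
  meaningful as ensembles and as qualitative outcomes, not node by node.
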