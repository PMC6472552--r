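---
title: "Modelling pneumoperitoneum with position-based dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pneumoperitoneum with position-based dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Laparoscopic surgery starts by insufflating the abdominal cavity with
CO~2~ to 10–16 mmHg. The resulting pneumoperitoneum displaces the
abdominal wall by several centimetres and compresses the viscera, so
preoperative CT no longer describes the intraoperative anatomy. `pneumosim`
simulates this deformation from three segmented surface meshes — abdominal
wall, viscera, and the deflated peritoneal boundary — so that surgical
planning (port placement, field-of-view rehearsal) can be done on a
geometry that resembles the insufflated patient.

## The mechanical model

The simulation is position-based dynamics (PBD): particles carry positions
and inverse masses, and each time step projects the positions onto
constraint manifolds instead of integrating forces. A step consists of a
damped semi-implicit prediction followed by `solver_iterations`
Gauss–Seidel rounds over four constraint families, in a fixed order that
the results depend on (and which is therefore part of the model
definition): distance constraints, the global volume constraint,
shape-matching clusters, then inter-body particle collisions. Velocities
are recovered from the position delta. Gravity defaults to zero: the
deformation of interest is driven entirely by insufflation, and all scans
and simulations share the same supine pose.

**The inflatable.** The deflated cavity mesh becomes a cloth: one particle
per vertex, one distance constraint per unique edge at its rest length
(the *spring stiffness* parameter), plus a single global volume constraint
over all faces,

$$C(\mathbf{x}) = V(\mathbf{x}) - k_p V_0,$$

where $V$ is the signed enclosed volume, $V_0$ the deflated volume, and
$k_p$ the dimensionless *simulation pressure parameter* — an overpressure
expressed as a volume multiple, not a physical pressure. The projection
moves each particle along the scaled constraint gradient
$\Delta\mathbf{x}_i = -s\, w_i \nabla_i C$ with
$s = C / \sum_j w_j \lVert\nabla_j C\rVert^2$. Bending links (distance
constraints between the opposite vertices of adjacent triangles) are
available via `bend_stiffness` but default to off; on the phantom they did
not improve the equilibrium shapes.

**Soft bodies.** The wall and viscera are Poisson-disc sampled on their
surfaces at spacing $2r$ ($r$ is the *particle radius*) and grouped into
overlapping shape-matching clusters: each cluster extracts the rotation of
its rest shape by polar decomposition of the moment matrix and pulls its
members a *cluster stiffness* fraction towards the rigidly transformed
rest configuration. Small overlapping clusters alone leave a thin particle
shell with essentially no resistance to large smooth indentations — any
deformation whose wavelength exceeds the cluster diameter is locally
near-rigid for every cluster. A particle-engine soft body avoids this by
filling the solid with particles; since this package samples surfaces
only, `build_soft_body` adds a second, coarser cluster level (3× spacing
and radius, same stiffness) to supply the missing long-wavelength
stiffness. Both soft bodies share one cluster stiffness, as in the
calibrated model.

**Stiffness semantics.** All stiffnesses live in [0, 1] and are applied as
$k' = 1 - (1-k)^{1/n}$ per iteration for $n$ solver iterations, so that a
given value means the same thing regardless of the iteration count.

**Contacts.** Collisions act only between particles of different bodies.
A pair closer than the contact distance $d_c = 2r + \text{margin}$ is
pushed apart along its separation direction, proportionally to inverse
masses — but the contact distance is capped at the pair's rest-pose
separation. The deflated cavity legitimately lies closer than $d_c$ to
both neighbours; the cap keeps such adjacent structures from
interpenetrating beyond their rest configuration without pushing them
apart spuriously. Candidate pairs are gathered once per step from a
spatial hash with a 1.5× search slack.

**Fixation.** Every particle below the plane
$y < y_{\mathrm{CoM}} - 20\,\mathrm{mm} \times \text{scale}$ (viscera
centre of mass, anterior/posterior axis) gets inverse mass zero: the
subject rests on its back. The +y-anterior supine convention is required
of all inputs; meshes in other orientations must be pre-rotated.

## Mesh processing

Meshes are read and written in STL (ASCII and binary), PLY (ASCII and
binary little-endian) and OBJ; units are millimetres throughout, never
guessed. STL carries no connectivity, so vertices are merged at 1e-6 mm on
load. Segmentation artefacts are smoothed with the volume-preserving HC
Laplacian (defaults `alpha = 0`, `beta = 0.5`, 10 iterations — the
algorithm's customary values; on a noisy closed sphere ten iterations
change the enclosed volume by under 0.5% while removing most radial
noise). The workflow scales all meshes to half size before simulation
(`scale_factor = 0.5`) and rescales extracted results and errors by 2;
every distance metric in the package is exactly linear under uniform
scaling, which is what makes this valid.

## Metrics

* `mean_nearest_vertex_distance` — the calibration error: one-sided,
  vertex-to-vertex, simulated → reference, averaged. A symmetric variant
  is behind a flag. Bit-equal to the O(n²) brute force.
* `voxel_overlap_error` — the validation error: meshes are voxelised at
  1 mm (cell centre inside-test by ray parity; grid origins snapped to the
  spacing lattice so grids are always mutually aligned), and the error is
  the count of voxels occupied by exactly one volume, also expressed as
  $100\,|A \triangle B| / (|A| + |B|)$.
* `hausdorff_distance` — symmetric: deterministic barycentric-lattice
  samples on either surface, distance to the closest point on the other
  surface's triangles; `max` over both directions, `mean` area-weighted.
* `geodesic_distance` — Dijkstra on the edge graph, refined on the
  corridor around the initial path by a Steiner graph (3 points per edge,
  all boundary nodes of each corridor triangle interconnected). An upper
  bound on the exact polyhedral geodesic; midpoint-only subdivision was
  rejected because it leaves the lattice directions unchanged and cannot
  improve the worst-case stretch. Within ~1% of great-circle lengths on
  sphere fixtures.

## Calibration and the pressure map

`run_grid_search` is the exhaustive four-dimensional search over cluster
stiffness {0.4…0.8}, spring stiffness {0.1…1.0}, particle radius
{2.2, 2.7, 3.3} mm and $k_p \in [1, 15]$ in 0.5 steps. For each parameter
set the scene is rebuilt, each pressure simulated to equilibrium, and the
extracted inflatable scored against the reference. The winner minimises
the subject-averaged per-subject minima; ties break to the smallest
parameter tuple; a parameter set with any non-converged (missing) cell
cannot win.

The pressure map is a cubic $y = a_3x^3 + a_2x^2 + a_1x + a_0$ from $k_p$
to mmHg. The published coefficients (0.038, −0.57, 3.4, −2.9) ship as
`default_pressure_map()`. The default fit is unconstrained least squares
with the (1, 0) initial-configuration point included as data — this
reproduces the published polynomial's behaviour, which evaluates to
−0.032 (not 0) at $x = 1$; an exactly anchored fit is available via
`anchor = c(1, 0)`. Reported pressures round to the nearest integer mmHg.
Inversion brackets sign changes on [1, 15] and refines by safeguarded
bisection; multiple roots are an error rather than a silent choice.

## The synthetic phantom

No CT data ship with the package; `make_phantom` builds a deterministic
stand-in: nested icosphere-based ellipsoids — a wall shell (outer semi-axes
160 × 120 × 260 mm, 15 mm thick by default), a viscera surface
(120 × 85 × 210 mm), and a thin two-sheet cavity of thickness `gap`
(3 mm) hugging the viscera at `gap/2` clearance. `make_inflated_reference`
fabricates the insufflated ground truth analytically: the cavity's outer
sheet and both wall sheets translate anteriorly by
$A(p)\,(\max(0, y)/b)^2$ with $A(p) = 40\,\mathrm{mm} \cdot p/16$ (the
reported "up to 4 cm" scale), while the inner sheet recedes posteriorly by
a compression fraction (default 0.5) of the same profile — insufflation
both lifts the wall and squeezes the viscera, and a reference whose inner
sheet never moves would sit trivially close to the deflated mesh under
every distance metric. The posterior half-space never moves (the fixed
back).

The phantom emulates: nested closed geometry, a thin deflated cavity, a
fixed back, anterior-dominant displacement of realistic magnitude, and
bilaterally symmetric landmarks (xiphisternum, pubic symphysis, umbilicus,
two ASIS) at canonical parametric positions. It does not emulate: organ
anatomy, contact with the table, heterogeneous tissue stiffness, CT noise,
or segmentation error. Passing the phantom tests therefore demonstrates
that the pipeline is mechanically and numerically coherent end-to-end —
not that it reproduces any particular subject.

On the phantom, the validation pipeline behaves as in the porcine
experiments: the voxel non-overlap error as a function of $k_p$ falls to
an interior minimum and rises again under over-expansion, and the mean
Hausdorff distance at the matched pressure is smaller than that of the
deflated input. The *calibration* vertex-distance curve does not show a
clean dip on the phantom: the analytic reference's smooth displacement
field and the particle model's wrinkled equilibrium decorrelate at the
individual-vertex level. This is a known limitation of comparing a
synthetic smooth reference with a particle simulation, not of the metric
implementations, which are all verified against closed forms and brute
force.

## Numerical choices

* Defaults: time step 1/60 s, 30 solver iterations, damping 0.05,
  equilibrium tolerance 1e-3 mm, 1000-step budget.
* The phantom experiments in the test suite use static relaxation
  instead: damping 1.0 (velocities discarded each step), 20 iterations,
  tolerance 0.05 mm, 500–600 steps. The Gauss–Seidel interplay of volume,
  contact and cluster projections leaves a persistent residual limit
  cycle of ~0.02–0.04 mm per step, so tolerances below that never
  trigger; 0.05 mm is still two orders of magnitude below the 5–6 mm
  accuracy scale of interest.
* Polar decompositions use a warm-started rotation-extraction iteration
  (always a proper rotation; degenerate moment matrices keep the previous
  rotation).
* Voxelisation jitters ray origins by ~1e-7 mm deterministically so rays
  never pass exactly through edges; ties in the grid search and in
  `match_pressures` break towards smaller parameters, documented rather
  than accidental.
* Determinism: surface sampling is seeded, the solver has no randomness
  and a fixed iteration order, so identical inputs give bit-identical
  trajectories.

## Problem sizes in the test suite

Tests run on reduced phantoms chosen so the fixed calibration radius
(2.7 mm) yields tractable particle counts: the validation phantom uses
wall 80 × 60 × 130 mm (8 mm thick), viscera 58 × 40 × 100 mm, gap 3 mm at
icosphere resolution 3 and scene scale 1.0 (~6k particles); the
grid-search phantom is a further 0.7× reduction at resolution 2
(~3k particles). The full-size defaults remain available for real use.

## Known limitations

* The inflatable's overpressure is a volume multiple, not a physical
  pressure; the cubic map to mmHg is an empirical correspondence.
* Surface-sampled soft bodies approximate volumetric tissue; the coarse
  cluster level restores long-wavelength stiffness but not volumetric
  incompressibility.
* Self-collision within a body, friction, and dynamic realism are out of
  scope: only the equilibrium geometry is meaningful.
* Geodesics are corridor-refined graph distances (upper bounds), not
  exact polyhedral geodesics.
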