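---
title: "Methods: exact CSG on molecular solids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact CSG on molecular solids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csgmol)
```

## The model

`csgmol` treats geometric solids as *exact* objects: a solid is anything that
can answer three questions analytically.

* `contains_point(s, p)` — is `p` inside the solid?  A point exactly on the
  surface is inside (closed solids).
* `intersect_segment(s, seg)` — for a segment `origin + t * direction`,
  `t` in `[0, t_max]`, the sorted disjoint closed intervals of `t` on which
  the segment is inside.
* `find_starting_cubes(s, lat)` — a few lattice cubes with at least one
  corner inside and one outside the solid, used to seed the surface search.

Leaf solids are spheres, tetrahedra and spindles; compound solids are
molecular (solvent-excluded) solids, triangle meshes interpreted as solids,
and CSG trees over all of these.  Because the leaves are analytic, CSG
results never accumulate approximation error — discretization happens only
once, at output meshing time, at a user-chosen resolution.  That matters for
the intended application: comparing binding cavities and electrostatic
regions whose meaningful differences can be smaller than a carbon atom
(tens of cubic Angstrom), where repeated mesh-on-mesh booleans degrade.

Meshing runs a marching-cubes engine on an axis-aligned cubic lattice whose
cube side is the resolution parameter (Angstrom).  Surface cubes are found
by breadth-first floodfill over face-adjacent cubes from each leaf's
starting cubes, merged, then filtered by corner classification against the
root expression.  Each lattice edge joining an inside corner to an outside
corner is intersected with the root's interval set (shared edges computed
once), and each surface cube is triangulated from a 256-case lookup table
indexed by its 8-bit corner-state mask.

### Spindles and the torus quartic

The spindle is the solvent-excluded region between two nearby atoms: the
volume inside a capped cylinder of radius $R$ (the circle traced by the
probe center) minus the interior of the coaxial torus of tube radius $r$
(the probe radius).  In the spindle's canonical frame (center at the
origin, axis along $x$) the torus is

$$(x^2 + y^2 + z^2 + R^2 - r^2)^2 - 4R^2 (y^2 + z^2) = 0.$$

Substituting the parameterized line gives a quartic in $t$; its leading
coefficient is $|d|^4 > 0$, so the monic form always exists (a lower-degree
`polyroot` fallback guards pathological inputs).  The roots are computed as
eigenvalues of the Frobenius companion matrix.  An eigenvalue counts as real
when $|\mathrm{Im}\,\lambda| \le 10^{-8}\max(1, |\mathrm{Re}\,\lambda|)$:
companion eigensolvers perturb double roots near tangency into conjugate
pairs, and this band recovers them.  Containment uses the rotational
cross-section rule: axial coordinate within the caps, radial distance
$\rho \le R$, and distance at least $r$ from the tube circle.  When
$R < r$ the probe reaches past the centerline and the spindle is *broken*:
the same formulas carve a hole through the middle, and the starting-cube
walk launches from both endcap centroids toward the center so both lobes
are seeded.

### Molecular solids

A molecular solid is assembled from the dual graph of the power diagram of
the atoms, weighted by the solvent-expanded radii $w_i = (r_i + r_s)^2$
(probe radius $r_s$).  This weighting is chosen so that the power vertices
of the expanded spheres are exactly the centers of probes tangent to four
atoms.  The regular triangulation is computed internally by the
empty-orthosphere definition — a 4-subset of atoms belongs iff its weighted
orthocenter has nonnegative power distance to every other atom — which is
$O(n^5)$ but correct by definition, including for degenerate inputs (a
deterministic $10^{-6}$ Angstrom jitter perturbs only the triangulation
combinatorics, never the primitive geometry).  This is an explicit scope
choice: the package targets structures of tens of atoms (binding-site
neighborhoods, fixtures); whole proteins would need an incremental
triangulation.

From the dual graph: one sphere per atom; one spindle per edge not longer
than $r_i + r_j + 2 r_s$ (beyond that no tangent probe can bridge the pair,
by the triangle inequality); one tetrahedron per dual tetra without such an
overlong edge; and for each dual triangle not between two tetrahedra, a
probe placed tangent to the three atoms (trilateration, up to two mirror
candidates).  A candidate colliding with no other atom becomes a *cup*: the
tetrahedron spanning the three atom centers and the probe center, minus the
probe-sized *negsphere* that carves the concave solvent boundary.
Containment and segment logic run over a 2 Angstrom spatial hash of
primitive bounding boxes; a point inside any negsphere is outside the solid
regardless of other primitives, mirroring the difference-boundary rule
below.

### Meshes as solids

A closed triangle mesh (for example an electrostatic isopotential surface)
becomes an exact solid by lattice classification: cubes holding triangles
are nonempty; empty cubes form face-adjacent connected components labeled
interior or exterior.  Components touching the lattice boundary are
exterior by definition.  The remaining components are labeled by ray
parity: a segment from a representative cube center to a point outside the
lattice, counting mesh crossings (odd = interior), with up to five
deterministic re-casts when a crossing is degenerate.  Parity labeling
subsumes naive outside-in alternation and is what resolves the thin-wall
abnormality, where an internal void's boundary shares cubes with the outer
surface and alternation would mislabel the void.  Points in nonempty cubes
are classified by majority vote over five segments cast to the nearest
empty-cube centers; each segment's crossing parity, combined with the
target component's label, casts one vote.  The five targets are the nearest
empty centers in deterministic order rather than random draws, so results
are identical across runs and worker counts.

### CSG semantics

Nodes combine operand answers: boolean logic for containment, interval-set
union/intersection/difference for segments, and the setwise union of
operand starting cubes (filtering early could lose disconnected components
of the output).  One boundary convention is global: the surface belongs to
the solid.  Consequently, for `A - B` a point on the boundary of `B` is
inside `B` and therefore *excluded* from the difference.  Interval
subtraction removes `B`'s closed intervals including endpoints, and
normalization re-closes at machine scale.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `resolution` | caller-set | Angstrom | lattice cube side; output mesh fidelity |
| `solvent_radius` | 1.4 | Angstrom | water-sized probe for molecular solids |
| `probe_large` | 5.0 | Angstrom | envelope probe bounding cavity extent |
| `ligand_sphere_radius` | 5.0 | Angstrom | ligand-neighborhood sphere radius |
| `workers` | 1 | — | forked workers for corner classification |
| `max_cubes` | 2e8 | — | lattice size cap (error suggests coarser resolution) |
| vdW radii | H 1.20, C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 | Angstrom | element table, overridable |

Cavity defaults follow the standard recipe: the cavity is
`(union of 5.0 A spheres on ligand atoms − molecular solid at 1.4 A probe)
∩ molecular solid at 5.0 A probe`, the large-probe envelope representing
space inaccessible to fragments larger than 10 Angstrom across.

## Numerical choices

* **Tangency separation** `1e-9` Angstrom: a segment grazing a surface
  yields two artificial intersection points at this separation (a
  degenerate interval), keeping interval topology consistent.  The value is
  a package choice; anything far below the resolution and far above machine
  epsilon behaves identically.
* **Boundary tolerance** `1e-12` Angstrom, absolute, for all containment
  comparisons, with "distance at most radius means inside".
* **Interval normalization** merges intervals separated by less than the
  tangency separation, preventing spurious zero-width exterior slivers.
* **Edge crossings** come from the root's interval boundaries; with several
  sub-resolution crossings on one edge, the crossing nearest the inside
  corner is used (consistent with the corner states).  If the interval set
  disagrees with the corner states — or the crossing sits at a lattice
  corner, where clipped intervals carry no interior boundary — the edge
  falls back to bisection on containment, which converges to the correct
  end.  Crossings within `1e-4` of an edge end are snapped onto the corner:
  this is far below the discretization error and lets coincident vertices
  weld exactly.
* **Vertex welding**: vertices with identical coordinates (crossings
  through a shared lattice corner) are merged and collapsed triangles
  dropped; this removes zero-area triangles while preserving closedness.
* **Marching-cubes table**: generated at load time from a face-local rule —
  on each face, crossed edges are paired so inside corners are separated,
  and on the ambiguous face (two diagonal inside corners) each inside
  corner is cut off.  Because the rule depends only on the face
  configuration, which adjacent cubes share, meshes are watertight by
  construction; no transcribed table, no transcription risk.  The directed
  segments (inside kept left, viewed from outside) chain into oriented
  cycles that are fan-triangulated with outward normals.  Mirror-image
  solids can differ in volume at the `1e-4` relative level because fan
  diagonals of non-planar cell polygons are not mirror-equivariant; this is
  a property of any fixed-table marching cubes.
* **Canonical frames** (spindles, jitter directions) are built by a
  deterministic largest-component pivot, so results are bit-reproducible
  across sessions and platforms.
* **Degenerate inputs**: coplanar atom sets get the combinatorial jitter;
  colinear atom triples yield no probe placement (logged); solids thinner
  than a cube that straddle no corner legitimately mesh to nothing — if no
  leaf yields a starting cube at all, the driver falls back to an exhaustive
  bounding-box corner scan with a warning.

## Parallelism contract

The floodfill is level-synchronous: the whole frontier is expanded, then
queues swap.  `workers > 1` partitions corner-classification batches across
forked processes (`parallel::mclapply`).  All stages are pure functions of
their inputs and the final cube, edge and vertex orderings are canonical
(sorted by lattice ids), so meshes are identical for any worker count; the
suite checks 1/2/4 explicitly.

## What the synthetic fixtures emulate — and what they do not

`random_primitives()` emulates stress collections of ~30 mixed primitives
with 0.5–3 Angstrom radii in a ±8 Angstrom box; `toy_molecule()` provides a
bonded dimer, a 4-atom tetrahedral cluster (side 4.0 Angstrom, radius 1.9,
the smallest molecule exercising every primitive type including cups), a
ring-plus-floor pocket with an optional blocking atom, and a helix-like
chain; `point_charge_grid()` samples bare Coulomb potential
$\phi = \sum_i q_i / |x - c_i|$ on a regular grid.

Passing tests on these fixtures demonstrate geometric and algorithmic
correctness — interval algebra, floodfill completeness, watertightness,
parity classification, steric monotonicity.  They do not demonstrate
behavior on crystallographic structures: real proteins bring thousands of
atoms (beyond the brute-force triangulation's comfortable range),
heteroatoms with curated radii, and Poisson–Boltzmann (screened) fields
rather than bare Coulomb ones.  The mesh-solid machinery is agnostic to the
field's physics, which is why Coulomb stand-ins are adequate for testing
isopotential extraction, but screening changes where real isopotentials
fall.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every code path at sub-minute cost per stage: spheres of 1–3
Angstrom meshed at 1.0 down to 0.125 Angstrom (up to ~22,000 triangles),
30-primitive unions at 0.5 Angstrom, molecules of 2–20 atoms at 0.25–0.4
Angstrom, 10^4-point containment comparisons, and 33-cube-per-axis
potential grids.  Finer resolutions only increase cube counts; the engine
is the same.

## Known limitations

* The brute-force regular triangulation is $O(n^5)$: practical to a few
  dozen atoms, deliberate for this package's scope.
* Features thinner than a lattice cube that straddle no corner vanish from
  meshes (acknowledged thin-spindle behavior); the corner scan fallback
  only helps when some corner is straddled.
* Face-adjacency floodfill does not propagate across corner-only contacts;
  components touching only at a corner are still meshed correctly because
  every leaf seeds its own floodfill.
* STL output is float32 by format; OFF/OBJ carry full doubles.
* No Poisson–Boltzmann solver is included or wrapped; grids are read
  (OpenDX) or synthesized (Coulomb).
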