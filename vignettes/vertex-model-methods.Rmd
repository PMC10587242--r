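---
title: "Vertex-model methods in vmtissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex-model methods in vmtissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmtissue)
```

## The model

`vmtissue` implements a vertex model (VM) of multicellular tissue in which
every physical statement ultimately resolves to a force on a vertex. A mesh
holds three kinds of objects: vertices (points $r_i(\mathcal{V})$ carrying
the dynamics), surfaces (ordered cycles of three or more vertices forming
polygons with straight edges, representing cells in 2D or cell faces in 3D)
and bodies (sets of four or more surfaces enclosing a volume, representing
cells in 3D). Vertices move by overdamped dynamics,

$$ f_i^{\mathcal{V}} = M^{\mathcal{V}} \frac{d r_i}{dt}, $$

integrated with forward Euler, positions clamped to an axis-aligned domain
(a no-flux boundary), and the out-of-plane coordinate pinned to zero in 2D
mode.

### Geometry through the fan triangulation

Every surface is measured through its fan triangulation: each pair of
adjacent cycle vertices forms a triangle with the surface centroid
$C_i^{\mathcal S}$ (the plain mean of the cycle positions). Triangle normals
are cross products of the corner positions relative to the centroid; their
norms are twice the triangle areas; surface area is the sum of triangle
areas; the surface normal is the normalized sum of triangle normals. Each
cycle vertex contributes half the area of each of its two fan triangles, so
vertex area contributions partition the surface area exactly — this
partition is what lets uniform surface quantities (tractions, normal
stresses) be distributed onto vertices without inventing weights.

Body volume uses the divergence theorem over the body's surfaces, with a
per-surface orientation flag $\alpha(\mathcal B,\mathcal S)=\pm 1$ relating
the surface's own cycle orientation to the outward direction. The flags are
computed once at body construction by testing the sign of each surface's
signed volume contribution about the body centroid; construction time is
the only point where the body is guaranteed geometrically sane, so that is
when the flags are fixed. Vertex volume
contributions scale the body volume by each vertex's share of the body
surface area, and per-vertex drag in variable-drag mode is the drag density
times that contribution (area-based in 2D). The default engine mode is a
fixed drag coefficient $M$ for every vertex.

Numerical choices: lengths and areas below $10^{-12}$ are treated as zero
when normalizing (degenerate triangles contribute nothing to normals or
gradients); a zero-length edge contributes zero to the line-tension force,
whose direction would otherwise be undefined — the vertex-merge operation
removes such edges anyway.

### Actors

An *actor* is a parameterized model bound to a mesh object or an object
type; bindings are additive, so the force on a vertex is the sum over every
binding that reaches it. Energy-based actors define
$f_i = -\partial \mathcal H / \partial r_i$ with analytic gradients (the
test suite verifies every one against central finite differences). The
built-in catalogue:

* quadratic constraints $\lambda (X - X^o)^2$ on surface area, perimeter,
  body volume and body surface area;
* edge tension $\lambda \sum \lVert e \rVert^p$ with $p \in \{1, 2\}$;
* adhesion, linear in the shared interface: shared-edge length between
  connected surfaces (keyed by unordered surface-type pair, counted once
  per edge) or shared-surface area between connected bodies; negative
  parameters favor interface, positive parameters compress it;
* uniform surface tractions and normal stress, distributed by vertex area
  contributions so the total applied force is exact;
* uniform body forces, distributed by vertex volume contributions;
* flat-surface and convex-polygon restoring constraints.

The functional forms of the two shape constraints are this package's own
constructions (only their intent -- restore flatness, restore convexity --
is prescribed): the flat constraint
pulls each cycle vertex toward the least-squares plane of the cycle with a
force proportional to its signed distance, and the convex constraint pulls
reflex vertices toward the chord joining their cycle neighbors, with the
reaction split between the neighbors. Both vanish identically on flat
convex polygons; they are explicit restoring forces, not energy gradients,
and are excluded from the gradient tests.

The shape constraints are applied automatically by the engine to every
surface (the convex constraint always, the flat constraint in 3D;
`engine_config(auto_shape_constraints = )` switches this off for purely
gradient systems). The automatic convexity force is not cosmetic: under
heavy merge/split activity a cycle can fold into a self-intersecting
polygon, and the fan-triangulation area of a folded cycle *grows* as the
fold deepens, turning the area constraint anti-restoring and destabilizing
the aggregate. Both the restoring force and the fold-deepening force grow
linearly with fold depth, so the automatic gain must exceed the model's
stiffest constraint modulus to win that race at any depth: the engine
default of 100 clears the demonstration models' stiffest modulus
($\lambda^{area} = 50$) while keeping explicit integration stable
(gain $\times\ dt \ll 2$ at both demonstration time steps). With it, the
cell-sorting model is stable at its stated time step; without it
occasional seeds destabilize mid-run (halving the time step also restores
stability, confirming the stiffness/topology interaction).

### Dynamic topology

Quality operations keep the mesh well conditioned without any cleanup pass
(every operation leaves the mesh valid):

* **vertex merge** (edge collapse) when two connected vertices come within
  the merge distance, refused if any incident cycle would drop below three
  vertices; the removed vertex is chosen by the seeded RNG and the survivor
  keeps its own position;
* **vertex split** from a force criterion: the total force on the
  candidate's connected vertices relative to the candidate defines a cut
  plane; connected vertices are partitioned by side (ties go to the
  positive side deterministically); each split vertex is assumed to carry
  half the candidate's force, and the split is accepted only if the total
  relative force on both sides points away from the plane — the new edge
  must be born in tension. Merge followed by an accepted split is a T1
  neighbor exchange;
* **surface demote** (T2) replaces a small surface by a vertex at its
  centroid, replacing its vertices in connected cycles (inserted once per
  cycle) and cascading removal of neighbors left under three vertices;
  refused for surfaces of four-surface bodies, so bodies never vanish this
  way;
* **body demote** removes a small body and everything it invalidates via a
  fixed-point cascade, then demotes each surviving boundary surface onto
  the vertex created at the body centroid;
* **vertex insert** (T3) inserts a penetrating vertex into the penetrated
  edge's cycle, connecting two colliding surfaces; detection is
  point-in-polygon plus a distance tolerance to the nearest edge, 2D only
  (and disabled whenever bodies are present).

Candidates are evaluated level by level (vertices, surfaces, bodies) in
increasing owner-id order, and each mesh object's connectivity can change
at most once per step. The evaluation is serial; because acceptance is
gated on disjoint affected sets, the accepted set equals what a race-free
parallel scheduler with the same priorities would produce. Demote
thresholds default to the merge distance squared (areas) and cubed
(volumes); the criteria are inherently qualitative ("too small"), so the
scale is tied to the one length threshold the user already sets.
The split distance must exceed the merge distance — twice the merge
distance by convention — or a fresh split would re-merge immediately.

### Particles: fibers and integrins

The hybrid subsystem models extracellular-matrix fibers as bead-spring
clusters: harmonic stretch between adjacent segment particles
($k^{tensile}(r - r^o)^2$), harmonic bending on interior triples
($k^{bending}(\theta - \theta^o)^2$, stress-free when straight), and a
Morse-form adhesion $k^{inter}(1 - e^{-a^{inter}(r - r^o)})^2$ between
segment particles of *different* fibers (adhesion without friction).
Integrins are particles bonded to one fiber segment particle
(harmonic) and to cell vertices through a linear potential
$k^{cyto} r$ whose negative coefficient yields a constant-magnitude
protrusive force pushing the bonded pair apart. All internal forces are
equal and opposite; particles obey the same overdamped update with
per-species damping.

The pairwise rule needs a truncation radius. The generic
default is three interaction widths beyond the rest length
($r^o + 3/a$, keeping >95% of the well depth). The migration demo instead
uses a contact-scale cutoff of three rest lengths (0.06 for the standard
parameters): a timescale analysis shows that with any multi-width cutoff a
fiber passing within 0.1 pulls with roughly 0.5 force units (tens of
in-range pairs), so a free mat aggregates into islands within one or two
time units — faster than every other process in the model and destroying
the substrate, whereas the migration scenario requires a substrate that
persists over the whole run. At contact scale, fibers adhere when they
touch and the free mat is metastable.

## The demonstration models

### Differential-adhesion cell sorting

Each cell is one surface with the energy

$$ \mathcal H(\mathcal S) = \lambda^{area}(A - A^o)^2
   + \lambda^{per}(L - L^o)^2
   + \lambda^{ten} \sum_j \lVert e_j \rVert
   + \tfrac12 \sum_{\mathcal S'} \lambda^{adh}(\tau, \tau')\,
     C(\mathcal S, \mathcal S'), $$

plus a random force of fixed magnitude and uniformly random in-plane
direction on every vertex, redrawn each step (it is a force, not Langevin
noise: no $1/\sqrt{dt}$ scaling, so its effect depends on the time step).
The standard parameters are: $dt = 0.0025$, merge distance $0.1$, split
distance $0.2$, random force $8.94$, $M = 1$, $A^o = 1$,
$\lambda^{area} = 50$, $L^o = 2\sqrt{\pi}$ (the perimeter of the unit-area
circle), $\lambda^{per} = 1$, $\lambda^{ten} = 10$ (type 1) and $20$ (type
2), and adhesion $-18 / -26 / -38$ for the 1–1 / 1–2 / 2–2 interfaces. The
aggregate starts as a square of unit-area cells with independent fair type
assignment, and sorting is tracked by the heterotypic boundary length
normalized by its time-zero value, sampled every 100 steps.

The reference run for the automated checks uses an 8×8 aggregate for
20,000 steps over five seeds; larger aggregates sort qualitatively the
same way but dominate the runtime of a routine test suite. With these parameters the
fractional heterotypic length falls well below one as like types
coalesce.

### Hybrid cell migration

A single unit-area hexagonal cell (area constraint $\lambda^{area} = 1$,
harmonic edge tension $\lambda^{ten} = 0.5$) sits on a fiber substrate
scattered between two sine walls and carries a fixed forward direction
($+x$). One hundred integrins are maintained by a per-step lifecycle: a
cytoskeleton bond breaks beyond $0.921$; an integrin outside the cell
polygon (boundary points count as inside) or with both bonds broken is
destroyed with its fiber bond; new integrins are created until the count
recovers, each anchored to a fiber segment particle whose distance from
the leading edge lies in $[0.0310, 0.155]$ — 5% and 25% of the initial
circumradius — and which lies under the cell polygon, since the integrin
is placed on the cell directly above its anchor (in-plane in this quasi-2D
setting). Distance from the leading edge is point-to-segment distance, so
anchors spread along the whole edge; referencing the edge midpoint instead
concentrates all anchors at the edge center, which stretches the edge
rather than propelling it. The two forward-most vertices at creation time
define the leading edge; existing bonds keep their vertices when the edge
changes. Topology is static in this model.

A note on the parameter set: the stated initial shape is a hexagon of area
1.0, whose circumradius is 0.6204, and the printed placement band
$[0.0310, 0.155]$ is exactly 5–25% of that value; the printed maximum bond
length 0.921 is close to, but not exactly, 150% of it (0.931). The printed
values are used verbatim.

Substrate geometry parameters without canonical values: amplitude 0.4 — at amplitude 1.0 with period 4 the channel rises more
steeply than a unit-area cell can follow and no anchor is ever eligible —
and fiber density 8 per unit channel area, which keeps the mean fiber
spacing well below the placement-band width so the mat has no holes that
starve the integrin lifecycle (at density 5 whole seeds pass with zero
eligible anchors). The substrate spans 1.5 periods.

Measuring the cell's mechanical footprint on the substrate is confounded
by the mat's own relaxation (fibers laid across one another jostle apart
slowly). `migration_fiber_response()` therefore runs a matched control with
zero integrins and the same seed — the substrate realization is identical
and no other stochastic input reaches the fibers — so the per-particle
difference against the control isolates exactly the cell-induced
displacement: fibers the cell never touched differ by zero.

With the standard parameters the cell migrates of order one length unit
per run before its leading edge runs out of eligible anchors (the strip
under the front edge depletes as anchored fibers are treadmilled backward,
and the fixed $+x$ bias can carry the cell off the channel at bends); the
direction of motion and the localization of fiber deformation to the path
are robust across seeds.

## What the generators do and do not emulate

The mesh generators produce ideal regular tilings (square grids, honeycomb
sheets, prisms) and the substrate generator produces straight, uniformly
random fibers in a sinusoidal channel. Real epithelial geometries are
disordered and real ECM fibers are curved, cross-linked and polydisperse in
thickness; passing tests on these synthetic inputs demonstrates the
correctness of the mechanics and topology machinery and the qualitative
behaviors (sorting, migration), not quantitative agreement with any
particular tissue.

## Known limitations

* 3D collision detection is absent; vertex insert is 2D-only and disabled
  when bodies are present, and there is no reverse T2 in 3D.
* Body splitting (3D division) is not implemented; surface splitting is.
* Periodic boundaries are not supported; the domain is a clamped box.
* Execution is serial; determinism is exact for a fixed seed.
* The random motile force is a plain force, so its stationary effect is
  time-step dependent.
* Snapshots are JSON; large states are better regenerated than stored.
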