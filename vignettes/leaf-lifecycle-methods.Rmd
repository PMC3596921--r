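---
title: "Methods: leaf meshing, mask-driven deformation and Markov senescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf meshing, mask-driven deformation and Markov senescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafcycle)
```

`leafcycle` models the seasonal decline of a broadleaf in three coupled
pieces: a geometric model of the blade, a physical model of how it curls,
and a stochastic model of how a population of leaves moves through
senescence states. This vignette records the modeling assumptions, the
parameters that matter, and the numerical decisions behind each piece.

## Boundary and mesh

The blade outline is a periodic interpolating cubic spline through ordered
key points, parameterized by chord length. Interpolation (rather than
approximation) was chosen because the key points are authoritative: they
are either hand-picked on a scan or generated exactly on a known silhouette,
and the curve must pass through them. `stats::splinefun(method =
"periodic")` supplies the spline; periodicity gives value and tangent
continuity at the closure. Sampling is uniform in arc length through a
1024-segment cumulative chord table — uniform boundary spacing is what lets
the triangle optimizer reach even edge lengths later. The default of 64
boundary samples resolves lobed outlines without inflating the particle
count; both the sample count and the spline evaluation are configurable.

Triangulation is incremental-insertion Delaunay (Bowyer–Watson over a
super-triangle), followed by edge recovery for every polygon edge and
culling of exterior triangles, i.e. a constrained Delaunay triangulation of
the polygon interior. Numerical guards: circumcircle membership uses a
relative tolerance of 1e-12 (cocircular points count as inside, so ties
resolve by insertion order, which is deterministic); every candidate cavity
is restricted to the edge-connected component around the triangle containing
the point; degenerate (zero-area) fan triangles abort with an error rather
than silently corrupting the mesh. Exactly duplicated input points are
rejected.

A boundary-only triangulation of an elongated leaf consists of long thin
triangles, so the mesh is improved by repeating two steps: (1) every
interior vertex moves toward the area-weighted centroid of its incident
triangles, and (2) edges are flipped until the local empty-circumcircle
criterion holds. The relocation is *smart* Laplacian smoothing: a move (or
its half- and quarter-step fallbacks) is rejected if it would invert an
incident triangle or lower the smallest incident angle. Plain Laplacian
smoothing can transiently worsen the worst angle; with the guard, and with
Delaunay flips (which never decrease the minimum angle of the quad they
act on), the mesh's minimum angle is non-decreasing after every full pass —
a property the test suite asserts pass by pass. Boundary vertices never
move and polygon edges are never flipped, so the triangulation always
partitions the same polygon: total area is conserved to 1e-9 across any
number of passes. The default of 160 passes is far past convergence for
meshes of a few hundred vertices (a second 160-pass run moves no vertex by
more than 1e-6); it is kept as the canonical default.

When a `target_edge` is supplied, interior refinement runs inside the loop:
centroids of triangles whose longest edge exceeds 1.5 × `target_edge` are
inserted (a 1→3 split plus flips), until the median unique edge length
reaches the target. If the median is still above target but no triangle
trips the 1.5× rule, the longer half of the triangles is split instead, so
refinement cannot stall short of its goal. Texture coordinates for inserted
vertices come from the same bounding-box normalization as the original
vertices: uv is the vertex position mapped into the unit square of the
*boundary* bounding box, with v = 0 at the bottom. That convention ties the
mesh to the mask map without requiring an unwrapping step.

## Mask-driven mass–spring deformation

The mesh is read as a particle system — vertices are particles, unique
edges are springs with rest length equal to the undeformed edge length.
Constraints are built by a flag traversal (visit particles in index order;
connect each to its not-yet-visited triangle neighbours), which produces
each undirected edge exactly once; the suite cross-checks the count against
an independent edge-set enumeration. Only structural springs exist: the
model deliberately has no shear or bending springs, because the structural
asymmetry that makes a real leaf curl is carried entirely by the mass
distribution, not by extra stiffness terms.

Masses come from the mask map, an 8-bit grayscale image indexed by the
vertex uv (nearest pixel, no interpolation — the mask is a painted label
map, and interpolating labels would blur region boundaries). The mapping is

* gray = 0 → mass 0.5,
* gray > 0 → mass ln(gray + 1),

so masses lie in [0.5, ln 256 ≈ 5.545] and grow monotonically but gently
with intensity. The explicit 0.5 branch exists because ln(0 + 1) = 0 would
create massless particles with infinite acceleration. Under a uniform
external force, acceleration scales as 1/m, so dark-painted regions (rim,
corners) out-accelerate bright ones (veins): painting the mask *is*
steering the deformation.

Integration is explicit Euler in the order acceleration → velocity →
position, with the new velocity used for the position update
(semi-implicit in position, as the update equations prescribe). The force
on a particle is the sum of linear Hooke spring forces, `−damping · v`,
and a configurable external field; the internal force law is the package's
own choice of the standard cloth-simulation form, since only the
integration and constraint equations are prescribed by the model. Units
are unspecified throughout — the simulator is unit-agnostic, and defaults
(`dt` = 0.005, stiffness 50, damping 0.1, unit downward force) are chosen
so that a leaf of diameter ≈ 4 length units deforms visibly within a few
hundred steps while `dt·sqrt(k/m_min)` = 0.05 keeps explicit Euler stable.

Explicit integration over-stretches springs, so after the velocity update
each spring's *predicted* next length is tested against
`(1 + τ_c) · rest_length`. An offending spring has its relative velocity
reduced along the predicted axis so the prediction lands exactly on the
bound; the correction splits equally between two free endpoints, or falls
entirely on the free one when the other is anchored. Because one
correction can re-violate a neighbouring spring, constraints are swept in
ascending index order repeatedly until a sweep finds no offender;
`n_constraint_passes` (default 2000) is a safety cap on those sweeps, not a
typical count — most steps need a handful, while a leaf hanging from its
petiole under load can need a few hundred for corrections to propagate
across the network. Sweeping to quiescence is what turns the per-spring
condition into a guarantee: after every step, every spring satisfies the
elongation bound, so with τ_c = 0.1 the maximum stretch over a whole run
is 10 % exactly. A fixed small sweep count would leave sub-percent
violations on heavily loaded steps.

Anchoring fixes all vertices within `anchor_radius` (default 5 % of the
bounding-box diagonal) of the petiole point (default: the leftmost boundary
vertex, matching the generator's convention of growing the blade along +x).
Fixed particles have identically zero velocity and acceleration; their
coordinates are bit-identical across the whole trajectory.

## Markov senescence

A leaf's state (texture label + deformation snapshot) changes at epoch
boundaries only; one epoch of duration `t` under environment `e` applies
one transition drawn from the matrix with diagonal
`P_ii = exp(−ln 2 · t / τ_i(e))` and off-diagonals
`(1 − P_ii) · X̃_ij(e)`. Two conventions make this a proper Markov chain:

* **Corner order.** Environment constants are stored in the fixed order
  dry-cold, dry-warm, wet-cold, wet-warm, interpolated bilinearly by
  normalized temperature (w) and humidness (h). Temperature and humidness
  are dimensionless in [0, 1]; mapping physical units onto that square is
  the caller's responsibility.
* **Row normalization.** The interpolated off-diagonal weights `X_ij(e)`
  of a row are renormalized to sum to one before being scaled by
  `1 − P_ii`; without this the rows would not be stochastic unless the
  user's constants happened to sum to one at every environment. A
  non-absorbing state whose weights vanish entirely is rejected as a
  specification error — a leaf must be able to leave it.

Absorbing states (the fallen leaf) get a diagonal of exactly one. Epochs
are discrete by design — the model's statement is about state at time t
versus t + 1, not a continuous-time jump process — so half-lives act
through the epoch duration in the exponent.

Population evolution draws one uniform variate per (leaf, epoch) from a
counter-based 32-bit hash stream keyed by (seed, leaf id, epoch). This
gives bit-identical histories for identical inputs, independence from
evaluation order, and no interference with R's global RNG. The sampler
sees only each leaf's current state, never its history, so the Markov
property holds by construction. The suite checks the stream's uniformity
indirectly: 10,000 leaves run for five epochs stay within three binomial
standard errors of the matrix-power distribution at every epoch and state.

## Synthetic fixtures and what they do not show

The generators stand in for scanned inputs:

* `make_outline()` produces an ellipse or a lobed polar silhouette
  `r(θ) = R(1 − depth·|sin(kθ/2)|^p)` with ≤ 2 % seeded radial jitter. It
  emulates the smooth, closed, non-self-intersecting contour of a real
  scan, not the asymmetry, serration or petiole notch of a particular
  species.
* `make_mask()` paints the region inside the outline with a uniform value,
  a dark edge band (exact point-to-segment distances, no raster
  approximation, so tests do not depend on mask resolution), or a bright
  vein corridor along the midrib. Real masks are hand-painted from a
  texture photograph and have soft gradients; the synthetic ones are
  two-level, which makes region membership unambiguous in tests.
* `make_default_spec()` builds a feed-forward chain with one absorbing
  final state, half-lives drawn in [5, 60] time units and forward weights
  decaying geometrically with the number of stages skipped — a plausible
  green → discolored → withered → fallen progression.

Passing tests on these fixtures demonstrates the algorithms' contracts
(bounds, conservation, convergence, distributional agreement), not fidelity
to any particular species' geometry or phenology.

## Problem sizes and runtime choices

The canonical test fixture is a 24-key-point maple outline sampled at 48
boundary points and refined to a 0.15 target edge (about 190 vertices / 330
triangles), deformed for 500 steps; the Delaunay cross-checks use 20 random
convex fixtures of at most 50 points against an all-triples brute-force
construction; the population checks use 10,000 leaves over five epochs.
These sizes keep the whole suite around a minute on one core while leaving
every assertion statistically and numerically meaningful.

## Known limitations

* No self-collision handling: a strongly curled blade can pass through
  itself.
* Single-layer model: the upper/lower surface asymmetry of a real leaf is
  represented only through the mask-derived mass field, not by a
  double-layered structure.
* No implicit integrator: very stiff springs require a smaller `dt` rather
  than a different solver.
* Mesh optimization assumes the boundary polygon is exact; there is no
  feature-preserving simplification or curvature-adaptive refinement
  beyond the target-edge rule.
* States carry opaque texture labels; rendering textured canopies is out
  of scope.
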