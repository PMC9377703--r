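---
title: "Methods: design-style views of channel structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design-style views of channel structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelkit)
```

channelkit turns a handful of illustration conventions — exploded views,
panoramic unrolling, contour slices, temporal condensation — into
deterministic geometry on atomic coordinates. This vignette documents the
models behind each operation, the parameters that matter, the numerical
conventions, and the known limitations.

## The canonical cylindrical frame

Every view assumes a channel with a roughly cylindrical shape and a
well-defined central axis. The package canonicalizes this as a
`SymmetryFrame`: axis → +z, axis origin → (0,0,0), azimuth reference → +x.
The membrane mid-plane is taken as z = 0 at the frame origin and the
extracellular side as +z; this is a convention, not a detection — nothing
in a coordinate file marks the membrane, so operations that need the plane
(vertical explosion) expose it as the `split_z` parameter (Å, default 0).

Two detectors are provided because ring-shaped channels defeat a single
rule:

* `inertia_axis()` takes the eigenvector of the coordinate covariance
  (gyration) tensor whose eigenvalue is *most distinct* — the one with the
  largest minimum separation from the other two. This handles both prolate
  assemblies (axis = largest eigenvalue) and oblate, disk-like ones
  (axis = smallest). If all three eigenvalues agree to a relative 1e-6 the
  structure has no distinct axis and the call errors rather than guessing.
* `cyclic_axis()` fits a least-squares plane through the subunit centroids
  and uses its normal. For a C~n~ oligomer with n ≥ 3 this is robust even
  when the gyration tensor is ambiguous, so it is the default whenever a
  partition with at least three groups exists (the CLI follows this rule).

Axis signs are canonicalized deterministically (component along +z
positive; exact ties prefer +x, then +y), so repeated runs and mirrored
inputs cannot flip views. `align_to_axis()` is a pure rotation +
translation; pairwise distances are preserved to machine precision, and
the same transform is applied to every trajectory frame so frames stay
mutually registered.

## Exploded views

`compute_layout()` produces per-fragment rigid *translations* — fragments
are never rotated, which keeps every part recognizable in the exploded
drawing. Radial mode translates each subunit by `radial_offset` (Å) along
the unit vector from the axis to its centroid, projected off the axis;
vertical mode splits each subunit at z = `split_z` and moves the halves by
±`vertical_gap`/2 along the axis; combined mode sums both. Offsets are
absolute distances rather than multiples of the centroid distance, so the
same offset produces the same visual gap on a small and a large assembly.
A subunit whose centroid projects onto the axis (< 1e-6 Å) has no defined
radial direction and triggers an error naming the subunit. Atoms exactly
on the split plane go to the lower fragment.

## Geometric abstraction

`abstract_subunits()` reduces each subunit to a coarse closed envelope in
three steps:

1. **Surface sampling.** `points_per_atom` points per atom on a Fibonacci
   sphere lattice (default 30). The lattice is deterministic — no RNG — so
   hulls are reproducible bit for bit. Points strictly inside another atom
   of the same subunit are discarded (tolerance 1e-9 Å, so tangent and
   concentric boundary points survive).
2. **Convex hull.** An incremental hull with a visibility tolerance scaled
   to the cloud extent; coplanar or collinear inputs error explicitly.
   Faces are oriented outward (positive signed volume).
3. **Decimation.** Iterative shortest-edge collapse to the edge midpoint,
   recomputing candidate edges after every collapse, until at most
   `target_vertices` vertices survive; the surviving set is re-convexified
   to restore closure.

Convexity is an accepted approximation: subunits of real channels have
concave faces, and a convex envelope overestimates them. The decimation
step has an intrinsic volume floor worth understanding: midpoint collapse
never moves a vertex outside the original hull, and the largest 12-vertex
polytope inscribed in a ball (the regular icosahedron) encloses only about
61 % of the ball. Decimating a finely sampled sphere to 12 vertices must
therefore lose at least ~39 % of the enclosed volume no matter how the
collapses are ordered; the implemented scheme measures ~57 % on that
fixture (the regression bound frozen in the tests). For presentation
purposes this is immaterial — the envelope is a shape cue, not a
volumetric measurement — but the hulls should not be used to quantify
volumes at aggressive decimation targets.

## Panorama unrolling

`unroll_surface()` places a virtual camera *on the channel axis* and spins
it 360°: one horizontal ray per (θ-bin centre, z-bin centre), θ measured
from the azimuth reference, counterclockwise seen from +z. Two readings of
"the surface" are provided:

* `side = "outer"` (default): the last sphere exit along the ray — the
  exterior silhouette.
* `side = "inner"`: the first boundary crossing ahead of the origin — the
  lumen-facing wall.

The surface is the van-der-Waals sphere boundary, not a solvent-excluded
surface; there is no probe rolling and no interpolation between rays. Rays
that hit nothing are recorded in a mask, not an error. The map is
rectangular in (θ, z) — nothing equal-area or conformal — and the hit
atom's scalar `property` (painted from a TSV or the imported B-factor) is
carried into a parallel matrix. PNG export min–max normalizes radii over
unmasked cells (masked pixels black, a constant map white) with θ
rightward and z upward; the TSV export is exact to the last digit
(`%.17g`), which is what makes byte-identical reruns possible.

## Pore geometry

The pore radius at height z is the radius of the largest probe sphere
centred **on the axis** at (0,0,z) that clashes with no atom:
r(z) = max(0, min~i~(‖c~i~ − (0,0,z)‖ − ρ~i~)). This is deterministic and
matches axis-slice illustrations; it underestimates the true pore wherever
the lumen meanders off-axis, which is the main difference from Monte-Carlo
pore finders that relax the probe centre laterally. Because r(z) is a
minimum of unit-slope cone functions it is 1-Lipschitz in z, a property
the tests exercise directly.

`find_constrictions()` reports strict local minima of the unblocked
profile (interior samples only; a flat plateau counts once, at its
leftmost sample), the k narrowest first, ties broken toward lower z. The
package deliberately does not hard-code which constriction is "the gate";
the choice of k and window is the user's, and `track_constriction()`
follows the windowed minimum across frames.

Contours (`slice_contour()`) reuse the inner-mode ray caster per θ bin.
Rays escaping between subunits are *open sectors* — legal values rendered
as gaps — while an axis point buried inside an atom has no contour at all
and errors.

## Temporal condensation

`condense_stack()` offers two algebras: `mean`, the pixelwise arithmetic
mean (uniform transparency 1/T; permutation-invariant, idempotent on
identical stacks, and the default), and `over`, sequential compositing
with opacity α in which later frames dominate — order-dependent by
design, kept for visual parity with stacked transparent prints.
`motion_average()` splats projected atom centres as normalized Gaussians
(`splat_sigma`, Å; default 1) and averages frames uniformly; averaging can
only lower peak intensity relative to the brightest single frame, which is
the quantitative signature of motion blur. Values stay in [0, 1] through
normalization, never through saturating arithmetic.

## The synthetic generator

`make_cyclic_assembly()` builds what the tests and the acceptance script
treat as the study conditions: a C~5~ assembly of 5 × 200 atoms
(carbon-like spheres, radius 1.7 Å) on a 16 Å ring spanning 20 Å of
height, mirroring the scale of a small pentameric channel without claiming
atomic realism. The `wall_column` template places each subunit's atoms on
a cylinder wall whose radius narrows at two built-in heights,
z = −0.4 h and z = +0.3 h (inner radii 0.5 and 0.35 × ring radius) —
an hourglass pore with two constrictions whose on-axis radii follow in
closed form from the construction, the narrower one on the +z
(extracellular) side. Constriction heights are snapped onto exact atom
z-levels so the ground truth is a property of the discrete structure, not
of an idealized continuum.

`make_twist_trajectory()` emulates gating: frame t (s = t/(T−1)) rotates
the z > 0 half by `twist_deg`·s about the axis and dilates the gate region
radially by 1 + `pore_open_frac`·s·exp(−((z−z~gate~)/w)²), opening the
pore linearly. The defaults (15° twist, 30 % opening over 8 frames) are
modest, gating-like magnitudes. Ground truth per frame is again computed
from the construction, never via the pore module, so tracking tests
compare two independent routes.

Noise is a single seeded Gaussian stream (`noise_sigma`, default 0 Å;
axis-recovery tests use 0.1–0.2 Å, the scale of coordinate uncertainty in
good experimental structures). The generator saves and restores the
caller's RNG state, and identical specs are bit-identical.

What the fixtures do *not* emulate: bonded geometry, secondary structure,
side-chain packing, heterogeneous radii, membrane atoms, or conformational
noise with spatial correlation. Passing tests therefore demonstrate the
correctness of the geometry — ray casts, hulls, profiles, layouts — under
known ground truth, not robustness to the full messiness of experimental
structures.

## Numerical conventions

* Rigid transforms and symmetry checks are asserted at 1e-9 Å; PDB
  round-trips at 1e-3 Å (the fixed-column precision of the format).
* The pore oracle used in tests is an independent binary search on the
  probe radius with an explicit all-atom clash test, converged to 1e-9 and
  compared at 1e-6 Å.
* Eigen-decompositions treat a relative eigenvalue spread below 1e-6 as
  degenerate ("no distinct axis") and a middle eigenvalue below a relative
  1e-12 as collinear.
* θ-bin k covers [k−1, k)·Δθ with Δθ = 360°/`theta_bins`; bin centres are
  sampled. Grids include both endpoints for profiles (`n_samples` evenly
  spaced) and bin centres for maps.
* Unknown elements never fail radius assignment; they take the default
  1.5 Å and are counted in a warning report. The bundled table is a
  standard van-der-Waals set (C 1.70, N 1.55, O 1.52, S 1.80, …).
* B-factor painting clamps to the printable column range [−99.99, 999.99].

## Problem sizes

The test suite and `scripts/acceptance.R` run on the generator defaults:
a 1000-atom pentamer for explosion, panorama-shift and hull checks; 100
seeded replicates of C~3~–C~8~ assemblies (5 × 40 atoms each) for axis
recovery; 20 random ≤ 50-atom assemblies for the pore oracle; an 8-frame
trajectory for tracking; and a 500-point sampled sphere for hull volume
checks. These sizes keep the full suite in the tens of seconds on one CPU
while exercising every code path at the study scale.

## Known limitations

* Pore radii are on-axis only; strongly kinked or off-centre pores are
  underestimated.
* Surfaces are van-der-Waals, not solvent-excluded; panoramas of deep
  crevices show the sphere boundary, not what a rolling probe would see.
* Hull abstraction is convex; concave subunit shapes are overestimated,
  and decimated volumes carry the floor discussed above.
* Dissection criteria for exploded views are chains and a single z-plane;
  arbitrary ontologies (domains, secondary-structure elements) are future
  work.
* PDB is the only structure format (fixed-column ATOM/HETATM, first
  altloc conformer, CONECT ignored); mmCIF and binary trajectory formats
  are out of scope.
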