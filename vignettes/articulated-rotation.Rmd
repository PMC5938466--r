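---
title: "Standardizing articulated 3D landmark configurations by rigid rotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing articulated 3D landmark configurations by rigid rotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artirot)
```

## The problem

Landmark coordinates digitized on articulated anatomical structures — a
humerus and radioulna meeting at the elbow, a skull and its mandible
meeting at the jaw joints — mix two very different kinds of variation:
the biological shape variation one wants to study, and nuisance variation
from the free motion of the joint and from the arbitrary orientation in
which each specimen happened to sit in the scanner.  Generalized
Procrustes superimposition removes orientation per *structure*, but it
cannot put two structures of the same specimen into a comparable
*relative* pose: the joint angle survives superimposition as spurious
"shape".

`artirot` removes this nuisance variation by strictly rigid means.  Each
structure is translated so that its articulation landmark sits at the
origin and rotated into a fixed reference pose; the second structure is
then swung to a user-chosen angle relative to the first.  Because every
motion applied is a proper rotation or a translation, per-structure shape
is mathematically untouched: all inter-landmark distances and the
handedness of every landmark quadruple are preserved to floating-point
precision.  The output is an ordinary joined landmark array ready for
downstream geometric morphometrics (which remains out of scope here, by
design).

## The geometric core

Write a structure's landmarks as points $p_0, \dots, p_M \in
\mathbb{R}^3$, with $p_0$ the articulation (base) landmark and $p_M$ the
end of the structure's main axis.  The standardization composes four
elementary operations:

1. **Translation.** Subtract $p_0$ (or more generally $p_0 -
   \mathrm{origin}$) from every landmark, pinning the articulation point
   to the origin: `translate_structure()`.
2. **Axis alignment.** To rotate the axis vector $u = p_M$ onto a target
   direction $v$, rotate within the plane the two vectors span: the
   rotation axis is the unit plane normal $N(u, v) = (u \times v)/|u
   \times v|$, the rotation angle is $\angle(u, v) = \arccos\!\big(u
   \cdot v / (|u||v|)\big)$, and the rotation itself is the axis–angle
   (Rodrigues) matrix $R'(N(u,v), \angle(u,v))$: `plane_normal()`,
   `vector_angle()`, `rotation_matrix()`, `align_rotation()`.
3. **In-axis (spin) correction.** Aligning one axis leaves one degree of
   freedom: spin about that axis.  It is fixed by a third, off-axis
   landmark $r_I$, rotated about the axis until it lies in a reference
   plane on a prescribed side.  The spin angle is computed with the
   two-argument arctangent of the landmark's two off-axis components:
   `in_axis_correction()`.
4. **Target placement.** The second structure, once in the reference
   pose, is swung about the $z$-axis so its axis points along
   $(\cos\theta_T, \sin\theta_T, 0)$, the unit vector forming the target
   angle $\theta_T$ with $(1,0,0)$: `vector_from_angle()`.

### Why the quadrant-aware arctangent

The spin angle for a constraint landmark with off-axis components
$(\alpha, \beta)$ is implemented as $-\operatorname{atan2}(\beta,
\alpha)$ rather than a single-argument $\arctan(\beta/\alpha)$.  The
single-argument form cannot distinguish diagonally opposite quadrants, so
for half of all inputs it would leave the landmark on the wrong side of
the reference plane — exactly the "mirrored placement" artifact the third
landmark exists to prevent.  With atan2, one rotation simultaneously
zeroes the landmark's out-of-plane coordinate and makes its in-plane
coordinate strictly positive, so no separate mirroring fix-up is needed.
This resolution of the mirrored placement is a *rotation*; it never
touches handedness.

### Degenerate inputs and tie-breaks

* Two vectors are treated as parallel when $|u \times v|/(|u||v|) <
  10^{-12}$; `align_rotation()` then returns the identity.
* For *antiparallel* vectors the in-plane rotation axis is undefined (any
  perpendicular axis works).  We choose, deterministically, the canonical
  basis vector most orthogonal to $u$ (ties broken in $x, y, z$ order),
  projected perpendicular to $u$, and rotate by $\pi$.  Determinism
  matters more than the particular choice: identical inputs must give
  identical outputs.
* The $\arccos$ argument is clamped to $[-1, 1]$ before evaluation, so
  floating-point drift can never produce a domain error.
* A rotation axis must be given as a unit vector ($|w| - 1 \le 10^{-9}$);
  a non-unit axis is an error, never silently normalized, because silent
  normalization hides bugs in the caller's geometry.
* A constraint landmark lying *on* the rotation axis (off-axis component
  below $10^{-9}$ relative to its norm) makes the spin correction
  undefined and raises a degenerate-geometry error naming the specimen.
* `inter_axis_angle()`, used to *measure* angles between standardized
  axes, evaluates $\operatorname{atan2}(|u \times v|, u \cdot v)$, which
  is algebraically the same angle as the $\arccos$ form but numerically
  stable near 0° and 180°, where $\arccos$ loses half the available
  precision.

## The two standardization procedures

**Single-point articulation** (`simple_rotation()`), for two structures
sharing one articulation point, takes three role landmarks per structure:
articulation point, axis end, and orientation landmark.  Structure 1 is
placed with its axis along $(1,0,0)$ and its orientation landmark in the
$xy$-plane at positive $y$; structure 2 is placed the same way and then
swung within the $xy$-plane to the target angle.  The result is returned
joined (structure 1's landmarks first), with a per-landmark provenance
attribute so `split_joined()` can recover the parts.

**Double-point articulation** (`double_rotation()`), for two detached
structures articulating at two hinge points, takes four role landmarks
per structure: the two hinge landmarks (the articulation axis passes
through both), an orientation landmark that removes the torsional spin
about the hinge axis, and a chirality landmark off the plane of the other
three.  Internally each structure undergoes the same two rotations as
above — axis alignment, then torsion removal — applied identically to
both structures, after which structure 2 is swung to the target angle.
The two rotated arrays are returned separately so the user can displace
one (`offset_structure()`) before joining, when the structures should not
be rendered in contact.

Both procedures translate each structure by its articulation landmark
internally.  Translation is idempotent — pre-translated data pass through
unchanged — so the separate `translate_structure()` step remains
available for workflows that want to inspect intermediate stages, while
a forgotten translation can never corrupt a result.

### Reference-frame conventions

A standardization is only useful if every choice in it is fixed, so these
conventions are part of the method's contract:

* structure 1's axis lies along $(1,0,0)$; its orientation landmark is in
  the $xy$-plane with positive $y$;
* structure 2's axis lies along $(\cos\theta_T, \sin\theta_T, 0)$; its
  orientation landmark is driven toward the $+90°$ in-plane rotation of
  its axis, which varies continuously with $\theta_T$ and coincides with
  structure 1's convention at $\theta_T = 0$;
* target angles are given in degrees in $[0, 360]$; the measured
  (unsigned) angle between axes equals $\theta_T$ for $\theta_T \le 180°$
  and $360° - \theta_T$ above that, since an unsigned inter-vector angle
  cannot exceed 180°;
* when `in_axis_correction()` is called directly without a `direction`,
  the default in-plane direction is the canonical basis vector most
  orthogonal to the axis — for axis $(0,1,0)$ this reproduces the
  classical correction angle $\operatorname{atan2}(r_3, r_1)$ driving the
  landmark to $(+, *, 0)$.

### Reflections are detected, not "repaired"

A mirror-digitized structure (a common artifact when landmarks are
transcribed from a mirrored scan) *cannot* be fixed by rigid rotation,
and silently absorbing it would corrupt the shape analysis downstream.
`double_rotation()` therefore checks the sign of the signed tetrahedron
volume of the four role landmarks across specimens: within a structure
all specimens must agree.  A specimen whose handedness disagrees with the
majority raises an explicit reflection error naming it.  With a single
specimen the intrinsic handedness is unknowable and no check is possible;
with an even split, the specimens disagreeing with structure 1 of the
first specimen are reported.  A coplanar role quadruple (volume zero)
is reported as degenerate instead, since its handedness is undefined.

### Landmark-quality screening

`check_landmark_quality()` warns — it never blocks — when role choices
make the geometry fragile:

* *coincident axis pair*: hinge landmarks closer than $10^{-6}$ times the
  structure's centroid size (the rotation axis direction becomes noise);
* *near-collinear roles*: the sine of the angle between the axis and the
  orientation landmark, measured at the articulation point, is below
  0.01 (the spin correction becomes unstable).

Both thresholds are scale-free, conservative choices; no principled
universal constant exists here, since what matters is the measurement
noise relative to the structure's size.  The classical advice that the
orientation landmark should share a coordinate with the axis landmark is
treated as guidance, not a requirement — the rotation is well defined
regardless — so the report carries the per-specimen deviation from that
advice as an informational attribute (`shared_coordinate_deviation`)
rather than a flag.

Specimens present in only one of the two datasets are dropped with a
warning listing their identifiers (never silently reordered or recycled);
matching is by specimen id, with the first dataset's order winning, so
input order is irrelevant but output order is deterministic.

## The synthetic specimen generator

`make_articulated_pair()` generates what the method is designed to
undo, with full ground truth.  One fixed, well-conditioned template shape
per structure is built in the standardized pose — articulation point at
the origin, axis landmark on $(1,0,0)$ (axis lengths 2.0 and 2.6 units,
loosely bone-like proportions), orientation landmark in the $xy$-plane,
chirality landmark above it, remaining landmarks scattered uniformly
around the axis.  Each simulated specimen is then the template pair posed
at a joint angle drawn uniformly from `angle_range_deg` (default
20–160°, a plausible flexion range for a limb joint) and subjected to an
independent random proper rotation (uniform random axis, uniform angle,
built with the package's own axis–angle primitive, which is in turn
cross-checked against an independent quaternion oracle in the test suite)
and a random translation per structure.  Optional isotropic Gaussian
noise is added to non-role landmarks only, so degeneracy is always
deliberate, never accidental.  Everything is reproducible from the seed,
and the caller's RNG stream is restored on exit.

Because all specimens share one template, the generator makes the
method's central property directly testable: with zero noise, every
standardized specimen must collapse onto the template configuration
exactly.  What the generator does *not* emulate — and what passing tests
therefore do not demonstrate — is realistic biological shape variation,
digitization error correlated along curves (semilandmarks are assumed
equidistantly placed beforehand), or joints whose motion is not a pure
rotation about the articulation; the generator validates rigid-motion
removal, not biological inference.

`make_degenerate_cases()` complements it with labelled fixtures (collinear
roles, coincident axis pair, a mirrored specimen, orientation landmark on
the axis) that each trigger one documented warning or error path.

## Problem sizes and numerical expectations

The test suite runs the full property battery at deliberately small desk
scale — 3–8 specimens, 12–15 landmarks per structure, 50 random rigid
motions per procedure, 100 random axis/angle/point triples against the
quaternion oracle — which already exercises every code path; the
standardization is exactly rigid regardless of size, so larger inputs
change runtime, not accuracy.  Observed reconstruction errors are at
machine-precision level (about $10^{-15}$ in the coordinate units);
the documented guarantees are stated conservatively at $10^{-9}$ for
rigidity and constraint satisfaction and $10^{-6}$ for end-to-end pose
invariance.

## Worked example

```{r example}
pair <- make_articulated_pair(n_specimens = 5, joint_type = "single", seed = 2018)
pair

joined <- simple_rotation(pair$structure1, pair$structure2,
                          land.a = 1, land.b = 2, land.c = 3,
                          land.d = 1, land.e = 2, land.f = 3, angle = 90)
parts <- split_joined(joined)
inter_axis_angle(parts$structure1, parts$structure2, 1, 2, 1, 2)

vector_from_angle(90)
```

```{r tps, eval = FALSE}
# round-trip through the TPS interchange format
write_tps(joined, "joined_arm.tps")
identical_back <- read_tps("joined_arm.tps")
```

## Known limitations

* Exactly two structures per call.  Assemblies of more than two
  independent subunits are handled by repeated application (standardize
  pairs sharing a reference structure), not by a dedicated n-structure
  operation.
* The choice of target angle is the user's.  A biologically implausible
  angle produces a geometrically valid but biologically meaningless
  configuration; when in doubt, analyses should be repeated at more than
  one angle.
* Reflection detection requires at least two specimens and assumes the
  majority is digitized consistently.
* Scaling, Procrustes superimposition and all downstream shape statistics
  are deliberately out of scope; the output arrays are meant to be passed
  to the standard geometric-morphometrics toolchain.
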