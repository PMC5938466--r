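# artirot

Standardized rigid rotations of articulated three-dimensional landmark
configurations.

## The problem

Three-dimensional landmark data digitized on articulated anatomical
structures — a humerus and radioulna meeting at the elbow, a skull and
mandible meeting at the jaw joints — carry nuisance variation that has
nothing to do with shape: the joint sat at a different angle in every
specimen, and every specimen was scanned in an arbitrary orientation.
Generalized Procrustes superimposition removes orientation per structure
but cannot standardize the *relative* pose of two structures from the
same specimen, so the joint angle leaks into downstream shape analyses
as spurious variation.

`artirot` is for morphometricians (and anyone else working with 3D
coordinate data) who need multi-part configurations made comparable
across specimens *before* Procrustes and shape statistics.  It removes
articulation-induced translation and rotation by strictly rigid means —
rotation and translation only, never scaling or reflection — placing the
two structures of every specimen at a user-chosen inter-structure angle.

## The method

For a structure with landmarks `p_0 … p_M` (`p_0` the articulation
point, `p_M` the end of its main axis), the standardization composes:

1. **translation** `p_i ← p_i − p_0`, pinning the articulation point to
   the origin;
2. **axis alignment**: the rotation carrying `u = p_M` onto a target
   direction `v` is the axis–angle (Rodrigues) matrix
   `R′(N(u,v), ∠(u,v))` with axis `N(u,v) = (u×v)/|u×v|` and angle
   `∠(u,v) = arccos(u·v / (|u||v|))`;
3. **in-axis (spin) correction**: the remaining spin about the aligned
   axis is fixed by rotating a third, off-axis landmark into a reference
   plane, using the quadrant-aware two-argument arctangent of its two
   off-axis components — which simultaneously resolves the "mirrored
   placement" ambiguity without ever touching handedness;
4. **target placement**: structure 2 is swung within the xy-plane so its
   axis points along `(cos θ_T, sin θ_T, 0)`, forming the requested
   angle `θ_T` with structure 1's axis on `(1, 0, 0)`.

`simple_rotation()` implements this for single-point articulations
(three role landmarks per structure); `double_rotation()` for
double-point (two-hinge) articulations (four role landmarks per
structure, with torsion removal and a cross-specimen chirality check
that reports mirror-digitized specimens instead of silently "fixing"
them).  Landmark data live in the field's standard `p × 3 × n` arrays
with specimen ids as dimnames; native `read_tps()` / `write_tps()`
handle the TPS interchange format with exact round-tripping.

## Worked example

```r
library(artirot)

# five synthetic specimens: one template pair under random joint angles
# and random per-structure rigid motions
pair <- make_articulated_pair(n_specimens = 5, joint_type = "single", seed = 2018)
pair
#> Synthetic articulated pair: 5 specimens, single-point joint,
#>   12 + 15 landmarks, joint angles 36.0-114.0 deg, noise sd 0, seed 2018

joined <- simple_rotation(pair$structure1, pair$structure2,
                          land.a = 1, land.b = 2, land.c = 3,
                          land.d = 1, land.e = 2, land.f = 3, angle = 90)

parts <- split_joined(joined)
inter_axis_angle(parts$structure1, parts$structure2, 1, 2, 1, 2)
#> spec_01 spec_02 spec_03 spec_04 spec_05
#>      90      90      90      90      90

vector_from_angle(90)   # the 90-degree target direction used above
#> [1] 0 1 0

round(parts$structure1[1:3, , 1], 6)
#>        x   y z
#> [1,] 0.0 0.0 0
#> [2,] 2.0 0.0 0
#> [3,] 0.9 0.8 0
```

Every specimen's joint now sits at exactly 90°, with structure 1's
articulation landmark at the origin, its axis on `(1,0,0)` and its
orientation landmark in the xy-plane — the random poses the generator
applied are gone, and only shape remains.  `plot_rotation_3d(joined)`
renders one specimen (structure 1 black, structure 2 red), and
`write_tps(joined, "joined_arm.tps")` exports for downstream analysis.

A command-line interface wraps the same functions
(`inst/cli/artirot`): subcommands `translate`, `rotate-simple`,
`rotate-double`, `plot` and `synth`, all operating on TPS files with
1-based landmark indices.

## Documentation

The methods vignette (`vignettes/articulated-rotation.Rmd`) describes
the geometry, the reference-frame conventions, degenerate-input
handling, the reflection policy, the quality screening thresholds, and
what the synthetic generator does and does not emulate.
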