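---
title: "Methods: averaging and morphometry of colored 3D facial surface scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: averaging and morphometry of colored 3D facial surface scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surface scanners used in orthodontics and craniofacial research (3dMD and
similar) deliver colored triangle meshes of the facial soft tissue —
roughly 10^4 vertices with per-vertex RGB — that are topologically dirty:
open at the neck and around hair, pierced by scanning holes, and littered
with non-manifold slivers and debris. To compare patients, build a
population norm, or follow one patient across treatment, all scans must be
put into dense point-to-point correspondence so that vertex *i* means the
same anatomical location on every surface. `morphoface` implements that
pipeline end to end: topology repair, spherical parameterization, dense
registration driven jointly by color and geometry, seven-parameter
Procrustes averaging, and signed distance / tensor-based / permutation
morphometry maps.

## Pipeline model and assumptions

**Topology repair.** Correspondence across surfaces of different topology
is ill-posed, so every scan is first made topologically spherical. Repair
proceeds in two stages. `remove_nonmanifold()` deletes duplicate faces,
resolves edges with more than two incident faces (keeping two faces,
preferring surface sheets over dangling fins — fewer boundary edges — and
larger area, and forcing the kept pair to be wound antiparallel so the
result stays orientable), splits non-manifold vertex fans by keeping the
largest-area fan, and keeps only the largest connected component by area.
`close_boundaries()` then sews each boundary loop with a centroid fan and
minimizes patch area by the standard linear proxy: a discrete-harmonic
(uniform Laplace) solve with the loop fixed, iterating a conforming
refinement (1-to-4 on interior patch faces, 1-to-3/1-to-2 next to the
loop, which cannot be split without cracking the neighboring surface)
until the relative area reduction falls below `rel_tol` (default `1e-3`)
or `max_rounds` (default 6) is reached. Every synthesized vertex carries
`filler = TRUE`, and filler is excluded from all matching and alignment
costs downstream, so hole-filled geometry can never influence the
statistics. Closed surfaces of genus > 0 are an error: handle cutting is a
different algorithm and deliberately out of scope.

**Spherical parameterization.** `spherical_parameterize()` maps the
closed genus-zero surface to the unit sphere in three stages: (1) a
conformal initialization — Gauss-map (vertex normal) seeding followed by
projected cotangent-Laplacian relaxation on the sphere (negative
cotangent weights clamped at zero for stability) until the per-iteration
displacement falls below 1e-7; (2) Moebius centering, iterating the
sphere Moebius transform until the source-area-weighted centroid is
within 1e-6 of the origin, which fixes the Moebius gauge freedom of the
conformal map; and (3) explicit area-equalizing relaxation, a tangential
gradient descent on the objective
$\sum_f (\text{area\_ratio}_f - 1)^2$, where the area ratio is the
spherical area fraction over the surface area fraction of face $f$. Each
stage is flip-guarded: a step is accepted only if no spherical triangle
reverses orientation, with step-halving otherwise. The balance between
conformality and area uniformity is exposed as `area_relax_iters` rather
than fixed, and `map_quality()` reports both distortions so the user can
audit the trade-off.

**Dense correspondence.** Registration happens on the sphere.
A robust initial warp comes from matched named curves (ten per face in
the intended protocol): each curve is resampled at equal normalized
3D-arclength, giving point pairs, from which `initial_warp()` first
estimates the single best global rotation (orthogonal Procrustes on the
pair directions) and then blends the residual per-pair rotation vectors
with normalized spherical-Gaussian weights. The global pre-rotation
matters: blending alone leaves ~0.02 rad of error even when the truth is
a pure rotation, which would dominate every downstream accuracy figure.

`fluid_register()` refines the warp greedily. The mismatch combines a
texture term — the negated sum over R, G, B of histogram mutual
information between the moving channels and the fixed channels sampled at
the warped positions — and a geometry term — the mean squared difference
of robust-z-normalized mean and Gaussian curvature (winsorized at ±6 MAD,
because curvature tails at feature apices would otherwise dominate the
quadratic cost). MI is summed per channel rather than computed as a joint
3-D histogram: at 10^2–10^4 vertices a joint 32^3 histogram would be
hopelessly undersampled. Curvature uses a squared difference rather than
MI because after robust normalization it is directly comparable across
subjects. Each iteration computes the per-vertex force as the negative
numerical gradient of the cost with respect to that vertex's tangential
displacement (central differences, h = 1e-3 rad; one displaced vertex
changes exactly one histogram sample, so the MI delta is an O(1)
incremental update), smooths the force field with a spherical Gaussian of
width `kernel_sigma` into a velocity, and composes the warp with the
re-projected tangential step. Steps are accepted only when flip-free and
cost-decreasing (step-halving otherwise), so the accepted cost trace is
strictly decreasing and the warp remains a bijection surrogate throughout
— the defining property of the fluid approach: regularize the velocity,
not the total displacement, and reach large deformations by composition.

The mismatch is evaluated only where neither side involves filler: a
sample is discarded whenever any positively-weighted vertex of the
interpolating fixed triangle is filler. This makes the cost *exactly*
invariant to filler colors, which the tests assert as an identity.

`kernel_sigma` is the resolution knob: it should match the spatial scale
of the deformation being sought. The package default is 0.1 rad; the
validation suite uses 0.2–0.3 rad because its synthetic deformations are
broad single bumps. A practical schedule for real data is a coarse pass
(0.3) followed by a fine pass (0.1), passing the first warp as `init`.

**Resampling and averaging.** `resample_to_reference()` pulls every
subject onto the reference topology by locating each reference direction
in the subject's warped triangulation (inverse warp) and interpolating
surface position, color, and filler. `generalized_procrustes()` then
alternates aligning each subject to the consensus with the weighted
closed-form seven-parameter (3 translation + 3 rotation + 1 uniform
scale) Procrustes fit — weights zero on filler, reflections refused via
the determinant-corrected SVD — and re-averaging. Sizes are standardized
by rescaling the consensus to the cohort mean centroid size. A literal
unit centroid size (`mean_size = "unit"`) is also available, but the
default keeps millimetres meaningful, because the display conventions of
the field (±5 mm individual maps, ±3 mm average-to-average maps) are in
absolute millimetres. `average_model()` reports the mean shape, a scalar
per-vertex variance (mean squared deviation; a full 3×3 covariance is a
possible extension but the per-vertex p-map only needs the scalar), mean
non-filler color, and the per-vertex filler fraction.

**Morphometry.** `signed_distance_map()` projects the subject-to-mean
displacement on the average's outward vertex normal — signed, in mm,
because the display convention (blue = inward, green = zero, red =
outward) requires a sign; unsigned Euclidean distance would fold the two
directions together. `colorize()` maps `lo → (0,0,1)`, `0 → (0,1,0)`,
`hi → (1,0,0)` piecewise-linearly and clamps outside. `tbm_map()` is the
surface analogue of the log Jacobian determinant: the per-face
log(subject area / average area), exactly invariant to rigid motion and
shifted by 2·log(s) under uniform scaling s. `permutation_pmap()` tests,
per vertex, the absolute difference of group-mean signed distances to the
pooled average against the relabeling null, `p = (1 + #{null ≥ obs}) /
(n_perm + 1)`; p-values are reported raw (with an optional
Benjamini-Hochberg column), since the choice of multiplicity control is a
study-level decision.

## The synthetic generator

Because no scan data ship with the package, `make_face()` /
`make_cohort()` generate 3dMD-like fixtures with *known ground truth*:
deformed icospheres (default level 3, 642 vertices, 80 mm radius) with
Gaussian feature bumps (nose 14 mm, brows, chin, lips, cheeks, eye
sockets), procedural skin-like color — a base tone, feature tints, smooth
whole-head marbling standing in for skin/hair tone variation, and a
channel-correlated per-subject hue shift that makes MI genuinely harder
than a squared color difference — plus per-feature height/position
jitter, per-vertex radial scanner noise, log-scale jitter, pose jitter,
and injectable defects (punched holes, non-manifold fins, debris
islands). All subjects share the template topology, so cross-subject
correspondence is vertex identity by construction, and a re-posed
"4-week" cohort regenerates the same subjects with new pose/noise draws.
Ten named curves (midline, eye rims, nose bridge, nostril line, lip
lines, jawlines, brow line) are traced through the feature anchors.

What the generator does *not* emulate: hair and eyelash geometry,
specular shading, expression change, scanner-specific hole patterns, and
texture atlases (color is per-vertex throughout). Passing tests therefore
demonstrate the correctness of the algorithms under controlled
variability, not scanner-specific robustness.

The marbling deserves a note: a warp over a region with constant color
and constant curvature is fundamentally unidentifiable by a
texture-plus-curvature cost, so a bald, uniform-albedo synthetic head
would make registration accuracy unmeasurable wherever the bump lands on
featureless skin. Real scans are not uniform-albedo anywhere.

## Numerical choices

- Curvature: cotangent-Laplacian mean-curvature normal and angle-deficit
  Gaussian curvature with barycentric (one-third) vertex areas. Angle
  deficit satisfies Gauss-Bonnet exactly; barycentric areas are always
  positive on obtuse triangles. At the 12 valence-5 seed vertices of an
  icosphere the pointwise error is bounded (~15 %) but does not vanish
  with refinement — a known property of the scheme; regular vertices
  converge.
- Spherical point location: exhaustive sign-consistent gnomonic
  barycentric test in compiled code, returning the best face even for
  edge/vertex queries; ties resolve to the first maximal face.
- Spherical triangle areas by l'Huilier's formula.
- Histogram MI uses equal-width bins over each variable's observed
  range, `0·log 0 = 0`; during gradient probes the binning is held fixed
  at the current sample range and out-of-range probes clamp to the end
  bins. A constant channel returns MI = 0 with a degenerate flag.
- PLY is written binary little-endian with double-precision coordinates
  (bit-exact roundtrip) and uchar RGB; color is [0,1] float internally.
- Vertex indices are 1-based internally (R convention); OBJ is 1-based
  on disk, PLY 0-based, converted at the I/O boundary.
- Degenerate inputs: zero-area faces are skipped with a warning in
  normal/area accumulation; rank-deficient (collinear) Procrustes
  configurations and sub-3-vertex boundary loops are errors.

## Problem sizes used in the validation suite

The test and acceptance runs use icosphere level 3 (642 vertices, 1280
faces), cohorts of 10 subjects, 999 permutations, 100 defect fixtures,
20 spherical-map seeds and 10 registration-recovery seeds, with
registration at `kernel_sigma` 0.2–0.3 and 30–80 iterations and boundary
closure at `max_rounds` 2–3 (patch refinement beyond that changes patch
area by well under 0.5 % while quadrupling patch faces). These sizes were
chosen as the smallest at which every property is meaningfully exercised;
all of them scale.

## Known limitations

- Greedy first-order fluid descent has a flat-basin floor: once the
  mismatch gradient vanishes (texture and curvature iso-contours),
  tangential sliding of ~0.01 rad is unconstrained. On an 80 mm head that
  is roughly 1 mm of correspondence uncertainty for strongly deformed
  pairs. Curve constraints and the global pre-rotation keep the practical
  error far below this for pose-dominated cohorts.
- Handle (genus > 0) removal, self-intersection repair, texture-atlas
  color, spectral/spherical-harmonic registration, and cluster-extent
  permutation inference are out of scope.
- The reference subject for group registration defaults to the first by
  input order; `reference_rounds` exposes an evolving-average iteration
  to reduce reference bias, but a full unbiased template estimation is
  not implemented.
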