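---
title: "Condition-based access-path planning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-based access-path planning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needleplan)
```

## The planning problem

Percutaneous needle interventions reach an internal target — a lesion in
the liver, say — through the skin, without an open surgical field. The
choice of insertion point fixes the whole access path, and a poor choice
risks puncturing vessels or organs, exceeding the needle's reach, or
producing a path the imaging and tracking setup cannot follow.
`needleplan` rates every point on a skin surface mesh as a potential
insertion point for a given target, using a condition-based scheme:
binary *hard conditions* exclude inadmissible paths, and continuous *soft
conditions* rate the admissible ones.

A candidate path is the straight segment from a sampled skin point
$\mathbf{s}$ to the target $\mathbf{t}$. Only non-intervention-specific
conditions are used, one hard and one soft condition per aspect:

| Aspect | Hard condition | Soft condition |
|---|---|---|
| Distance to risk structures | clearance $\ge$ safety margin | more clearance is better |
| Path length | path shorter than the needle | shorter (relative) paths are better |
| Insertion angle | angle to the vertical axis $\le$ 60° | smaller angle to the transverse plane is better |

Additionally a path must cross the skin exactly once (at the insertion
point): a segment that re-enters the skin through a fold has no usable
line of sight.

## Soft conditions and aggregation

Each soft condition yields a condition quality value (CQV) in $[0,1]$,
1 being optimal; all CQVs are clamped into $[0,1]$.

**Distance.** With clearance $d$ (minimum distance between the path
segment and any risk structure surface, evaluated up to a maximum of
$d_{\max} = 10$ mm) and safety margin $m = 2$ mm,
$$\mathrm{CQV}_{\mathrm{dist}} = \frac{d - m}{d_{\max} - m}.$$

**Path length.** Path length $L$ is rated relative to the target's
*vertical surface distance* $L_v$ (the depth of the target below the skin
along the vertical axis), so deep targets are not penalised simply for
being deep. With needle length $L_{\max} = 150$ mm,
$$\mathrm{CQV}_{\mathrm{path}} = 1 - \frac{L - L_v}{L_{\max} - L_v}.$$
If $L_v \ge L_{\max}$ (a target deeper than the needle can reach
vertically) the ratio is undefined; the implementation returns 1 when
$L \le L_v$ and 0 otherwise — the clamp-consistent limit — and warns.

**Angle.** In-plane paths are easiest to track on axial imaging, and CT
gantries can tilt by roughly 25°, so the angle $\theta$ between the path
and the transverse plane is scored piecewise linearly with breakpoint
$b = 0.9$ at the tilt angle:
$$\mathrm{CQV}_{\mathrm{angle}} =
\begin{cases}
1 - \theta\,(1-b)/25 & \theta \le 25^\circ\\
b - b\,(\theta - 25)/(60 - 25) & \theta > 25^\circ,
\end{cases}$$
clamped so that $\theta > 60^\circ$ scores 0. Both branches equal $b$ at
the breakpoint, so the score is continuous.

**Aggregation.** The path quality value is
$\min(\mathrm{CQV}_{\mathrm{dist}}, \mathrm{CQV}_{\mathrm{path}},
\mathrm{CQV}_{\mathrm{angle}})$. The minimum, rather than a weighted sum,
means a path can only score well if it has no weak condition; the
decision to accept a weakness in one aspect for a benefit in another is
left to the user, not folded into a trade-off weight.

### Two angle measures

The hard angle condition and the soft angle score use different
measures. The hard condition bounds the angle to the *vertical (sagittal)
axis* at 60°, which protects the line of sight of optical tracking; the
soft score uses the angle to the *transverse plane*, which measures how
far the path leaves the imaging plane. For a frame with orthonormal up
axis $\mathbf{u}$ and longitudinal axis $\mathbf{l}$ and unit path
direction $\mathbf{p}$:
$\theta_{\mathrm{axis}} = \arccos|\mathbf{p}\cdot\mathbf{u}|$ and
$\theta_{\mathrm{plane}} = \arcsin|\mathbf{p}\cdot\mathbf{l}|$. Both are
invariant to flipping the direction. For a vertical path in the
transverse plane both are 0; they coincide whenever the path stays in
the plane spanned by $\mathbf{u}$ and $\mathbf{l}$.

## Clearance: exact and incremental backends

The clearance of a path can be computed two ways, selected by
`clearance_backend` in `planning_params()`:

* **exact** (default): the exact minimum Euclidean distance between the
  path segment and every risk-structure triangle, capped at
  `max_eval_distance`. Per triangle this is zero on a transversal
  crossing, otherwise the minimum of the two endpoint-to-triangle and
  three segment-to-edge distances.
* **incremental**: a cylinder laid around the segment whose radius grows
  in steps of `clearance_r_step` (default 0.25 mm) up to
  `max_eval_distance`; the clearance is the last radius that overlaps no
  risk structure. A cylinder of radius $r$ about the segment overlaps a
  mesh exactly when the segment-to-mesh distance is below $r$, so the
  incremental result is the exact clearance floored to the radius grid —
  it never overstates safety, and the two backends agree within one
  `r_step` by construction. The incremental form is kept as a
  cross-check and because the stepped radius is itself a meaningful
  resolution statement; the test suite validates the shared distance
  kernel against an independent pure-R oracle (per-triangle 1-D convex
  minimisation along the segment) so the cross-check is not circular.

## Candidate sampling

The default sampler draws insertion-point candidates area-uniformly on
the skin: the number of samples is Poisson with mean
`sampling_density × area`, faces are chosen proportionally to area and
points uniformly within each face. The default density of 9 points per
mm² is the clinical reference rate; planning a whole torso at that rate
evaluates millions of candidates, so the command-line interface defaults
to 0.05 points per mm² and offers `--reference-density` to restore the
reference rate.

An alternative `"rayfan"` sampler casts quasi-uniform sphere directions
(a Fibonacci lattice, randomly rotated per seed) from the target and
keeps the first skin hit of each ray, mirroring a scanner that probes
the surface from the target outwards. Its surface density necessarily
varies with distance and incidence angle — a target-centred fan cannot
be area-uniform on the skin — which is why the uniform sampler is the
default and the fan is an explicitly separate mode.

## Hard-condition boundary semantics

Violations are strict: a path fails `risk` only when clearance is
*below* the safety margin (a path exactly at the margin is admissible,
with $\mathrm{CQV}_{\mathrm{dist}} = 0$), fails `length` only when
strictly longer than the needle, and fails `angle` only strictly above
60°. All violated conditions are recorded, not only the first, so
failure tallies are usable diagnostics; soft scores are *absent* (`NA`)
for hard-failed candidates rather than 0, so renderers can distinguish
unsuitable from worst-admissible.

## Visualization

Admissible insertion points are divided into four quality classes. The
class boundaries are equal-width quartile bins of $[0,1]$ (with the top
bin right-closed); nothing deeper than order preservation is claimed for
them and they are configurable. Classes map onto a four-step single-hue
green scale (ColorBrewer "Greens"), darker meaning better. Three display
modes exist: *full* (class colours), *area* (one uniform colour for all
admissible points) and *baseline* (nothing shown). Unsuitable points are
hidden in every mode.

The heatmap rasteriser paints each candidate's colour at its texture
coordinate and fills texels between samples from their nearest candidate
within one sampling spacing; texels whose nearest candidate is
hard-failed stay black. Assigning texels to the nearest candidate over
*all* candidates (rather than dilating only the admissible ones) makes
the lit texel area an unbiased estimate of the admissible skin area,
which the tests verify against the analytic admissible-cone area on a
slab scene.

The target overlay computes the geometry shared by three target display
concepts: the target's vertical projection onto the skin and its depth,
encoded as a 15-segment ring filled one segment per centimetre, a
reference line of 10 mm × 2.5 mm cylinders (one per started centimetre),
a 20 mm sphere at the target, and a pin label with the depth in
centimetres to exactly one decimal.

## The phantom generator

No patient data ships with the package; scenes are generated.

* **Slab scenes** (`make_slab_scene()`): a planar skin at $z = 0$ with
  targets on the vertical axis and sphere/tube risks below. Everything
  is closed-form: $L_v$ equals the target depth, the clearance of the
  vertical path from a lateral sphere at offset $o$ with radius $r$ is
  $o - r$, and the admissible region of the hard angle condition is the
  disc of radius $\mathrm{depth}\cdot\tan 60^\circ$. These closed forms
  are the oracles for the unit and acceptance tests.
* **Torso phantoms** (`make_torso_phantom()`): a closed ellipsoid skin
  (default semi-axes 150 × 200 × 100 mm, desk-scale torso proportions)
  with a longitudinal tube emulating a major vessel and a sphere
  emulating an organ at risk, both checked to lie strictly inside the
  skin and clear of every target. Texture coordinates come from a
  cylindrical unwrap about the longitudinal axis. Generation is
  deterministic.

Sphere risks and the torso skin are icospheres; at the default
subdivision level 3 the sagitta (radial shortfall of a face centre) is
below $0.005\,r$, i.e. under 0.05 mm for a 10 mm sphere. That bound sets
the analytic-versus-mesh tolerances in the tests. Because the icosphere
is inscribed, mesh distances to a sphere risk are never *smaller* than
the analytic sphere distance — tessellation errs on the safe side.

What the phantoms do not emulate: real skin topography and folds,
heterogeneous tissue, deformation and respiratory motion, and
segmentation noise. Passing tests on phantoms therefore demonstrate the
correctness of the geometry and scoring pipeline, not clinical validity
on patient meshes.

## Numerical choices

* Units are millimetres; frames are right-handed with $+z$ vertical
  (anterior, supine patient) and $+y$ longitudinal (cranial) by default,
  configurable per scene.
* Ray/segment-triangle intersection uses Möller–Trumbore with a
  barycentric slack of $10^{-10}$, so a crossing exactly on an edge
  shared by two faces is reported by both and then deduplicated by
  clustering intersection parameters within $10^{-9}$ mm — a grazing
  contact counts once.
* Crossing counts include segment endpoints (with the same tolerance):
  the planner's line-of-sight condition asks whether the target-to-skin
  segment crosses the skin exactly once, and that single crossing *is*
  the insertion endpoint.
* Point-in-mesh tests use crossing parity along the frame's up axis,
  minutely perturbed to avoid grazing vertices of symmetric meshes; for
  open slab skins this reads as "below the surface", which is the
  intended meaning there.
* Degenerate (zero-area) faces are dropped when meshes are constructed
  or loaded.
* Clearance is capped at `max_eval_distance` *before* scoring, so the
  distance score saturates at exactly 1 cm with defaults.

## Problem sizes in the tests

The test suite and the acceptance script run planning at reduced
sampling densities (0.005–0.02 points per mm² on 120–200 mm slabs,
roughly 100–800 candidates per map) and icosphere levels 2–3; these
sizes keep the whole suite under a few tens of seconds while leaving
every property measurable — e.g. the admissible-cone radius check has
about 400 candidates against a 10 mm sampling spacing. The density
acceptance check itself runs at the full 9 points per mm² on a
20 × 20 mm slab (~3600 samples).

## Known limitations

* Straight rigid paths only; no curved or steerable needles.
* Meshes are assumed static: no deformation or respiratory compensation.
* The heatmap treats texture space as approximately isometric to the
  surface when converting the sampling spacing to texels; strongly
  distorted unwraps (near the poles of the cylindrical torso unwrap)
  will over- or under-fill locally.
* Intervention-specific conditions (organ trajectories, electrode
  spacing rules, ablation margins) are deliberately out of scope.
* The brute-force nearest-candidate search in the vertex colouring is
  quadratic at heart; it is fine at planner scale but would want a
  spatial index for millions of candidates.
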