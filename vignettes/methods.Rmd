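---
title: "Simulating markerless structured-light navigation for pedicle punctures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating markerless structured-light navigation for pedicle punctures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pednav)
```

## The problem

Posterior cervical pedicle screws travel a corridor a few millimetres wide,
flanked by the vertebral artery and the spinal cord. Markerless
structured-light navigation addresses this by scanning the exposed surface
with a coded-light camera, registering the scan to the preoperative CT
model, and tracking the drill sleeve directly in the same camera frame, so
that one sensor provides both registration and instrument guidance.
`pednav` rebuilds that pipeline as a simulation so every stage can be
measured against ground truth: how well the registration recovers the true
patient pose, how well a partial sleeve scan localises the instrument axis,
and how far the resulting wire lands from the plan.

All lengths are millimetres, reported angles degrees (radians internally).
Two frames are used throughout: the *image* frame of the preoperative
meshes and the *world* frame of the camera, linked by an explicit rigid
transform. Line angles are undirected and folded into [0°, 90°], because a
wire's direction sign is arbitrary.

## The phantom

`phantom_spec()` / `make_scene()` build a rigid stand-in for an
experimental spine model: `n_vertebrae` (default 7) watertight capped
elliptic-cylinder bodies (half-axes about 9 × 25 × 20 mm, ±6% seeded
variation) stacked 5 mm apart, each carrying two pedicle corridors —
straight 3 mm-radius cylinders running postero-lateral to antero-medial at
about 25° convergence in the mid cross-section. Construction fails if a
corridor cannot keep a configurable cortical margin (default 1.5 mm) over
the central half of its 24 mm grading span. The skin is a smooth lofted
offset surface: elliptic cross-sections inflated by `skin_offset`
(default 20 mm, a typical soft-tissue layer) with gentle axial modulation.
The modulation plus the elliptic cross-section remove the translational
and rotational sliding modes that would otherwise make surface-based
registration ill-posed on a symmetric shape. Vertebra geometry is
deliberately parametric rather than anatomical: the accuracy metrics
depend only on surfaces and corridor axes, and straight circular corridors
give the breach depth a closed form. One deliberate simplification: the
body is a single elliptic cylinder with no posterior-element block, so
entry and exit points lie on an analytic ellipse chord and every geometric
test has an exact expected value.

The scene also designates six landmark points on the posterior skin
surface, spread along the spine and alternating across the midline — the
synthetic counterpart of the anatomical landmarks an operator picks for
rough registration. Ground-truth planned trajectories (radius 1 mm,
length 300 mm) are coaxial with the corridors.

Determinism: everything derives from the spec seed; identical specs export
byte-identical STL files.

## Scan simulation

`simulate_scan()` models the structured-light camera as a pinhole with
frustum half-angles from the reference field of view (800 × 605.8 mm at
1500 mm). One ray is cast per grid sample; only the first surface hit
survives (hidden-surface removal), hits outside the 900–2900 mm working
range are dropped, and so are hits beyond an 80° grazing-incidence cutoff
— structured-light returns degrade at grazing angles, and the exact cutoff
is a package choice. Gaussian depth noise (`depth_sigma`) is applied along
the viewing ray; `add_outliers()` appends a configured fraction of
uniform box outliers. The default test grid is 150 × 200 (desk scale);
the physical camera's 3 MP resolution is reachable but unnecessary for
the properties under test. What this generator does *not* emulate —
fringe decoding, exposure and texture effects, specular dropout,
soft-tissue deformation, respiratory motion — bounds what passing tests
say about real data: they validate the geometry and estimation stack, not
the optics of any particular scanner.

The depth-noise magnitude of the real camera is unpublished, so noise
levels are swept in tests rather than fixed: the registration checks run
at σ = 0 and σ = 0.1 mm, the cylinder-fit checks at σ = 0.05 mm.

## Registration

The pipeline is deliberately two-stage, in the order an operator would run
it: landmark rough alignment, SOR denoising, ICP fine registration.

* `rough_register()` solves the least-squares rigid transform (rotation +
  translation, no scale) over at least four ordered landmark pairs via the
  SVD (Kabsch/Umeyama); fewer than four pairs or a collinear set is
  refused.
* `sor_filter()` removes points whose mean distance to `k = 6` nearest
  neighbours exceeds the global mean by more than one standard deviation
  of that statistic (the common SOR parameterisation in point-cloud
  tooling); a tiny absolute epsilon keeps exactly-tied statistics from
  being split by floating-point noise.
* `icp_refine()` iterates closest-point correspondence against the surface
  mesh with a linearised point-to-plane update (the classic
  point-to-surface formulation; correspondences to the nearest triangle,
  normals from the hit facet), stopping when the RMS change falls below
  1e-6 mm or at 100 iterations. Point-to-plane was chosen over
  point-to-point Kabsch updates because the latter stalls in tangential
  sliding modes on smooth surfaces — observed as a plateau two orders of
  magnitude above the achievable residual. For point-cloud targets the
  update falls back to Kabsch. Iterations may run on an evenly spaced
  subsample (default cap 5000); the reported RMS is always recomputed
  over *all* source points at the final pose. No trimming is applied by
  default.

Two scalars summarise a registration, matching how such systems report
quality: the final ICP correspondence RMS, and the *registration accuracy*
defined here as the mean unsigned cloud-to-mesh distance of the registered
scan — a mean (not median or RMS) because only a mean over a
fine-registered cloud plausibly reaches the ~0.01 mm scale reported for
such systems. `register_map()` then applies the *inverse* transform to the
whole navigational map (skin, bones, channels), flipping its frame tag so
a second application is refused.

## Instrument tracking

`fit_cylinder()` estimates the drill-sleeve axis from a partial surface
scan. Because the instrument diameter (25 mm) is entered into the system,
the radius is held fixed and only the 4-DOF axis is estimated — this is
what stabilises fits from a narrow visible arc. Hypotheses come from
RANSAC over two points plus their (scan or PCA-estimated) normals: the
axis direction is the normal cross product, the axis point sits one radius
beneath a sample along its normal. The best-scoring hypothesis is refined
by Levenberg-Marquardt on the radial residuals (`minpack.lm`), inliers are
points within 0.3 mm of the surface, and a fit is *failed* — a signal,
not an error — when fewer than 50 usable points remain or the inlier arc
coverage drops below 90°, mirroring how a navigation system must survive
occlusion. A free-radius mode exists for diagnostics. The axis sign is
fixed tip-ward (positive component along the camera viewing axis), the
insertion direction; the navigation channel built from a fit is coaxial
with it at the configured 2 mm diameter and 800 mm length.

`simulate_alignment()` stands in for the manual gimbal-and-rod
adjustment: it repeatedly applies the guidance offsets (perpendicular miss
of the planned entry from the current axis, and the axis angle) scaled by
a gain (default 1, i.e. one exact correction) until both tolerances are
met. It always converges for rigid corrections; the trace is recorded.

## Evaluation

`entry_exit_points()` intersects the wire axis with the bone mesh: entry
is the first crossing along the insertion direction, exit the last within
the channel length (anterior cortex penetration). Offsets are Euclidean
distances between corresponding points; per-axis differences are signed,
preoperative minus postoperative. Breach depth against a corridor is
`max(0, d + r_wire - r_corridor)` where `d` is the wire-axis distance from
the corridor axis over the overlapping span; the squared distance is a
convex quadratic along the wire, so the maximum sits at a span endpoint
and is evaluated in closed form. Grades follow the standard breach bands:
0 (contained), 1 (< 2 mm), 2 (2–4 mm), 3 (≥ 4 mm). On the phantom the
"postoperative hole centre" is the achieved-axis/mesh intersection — no
drilling artefact is simulated, a stated modelling simplification.

`summarize_metric()` reports mean, sample sd, median and quartiles;
`paired_location_test()` checks normality of the paired differences
(Shapiro-Wilk at α = 0.05) and branches to a paired t test or the
Wilcoxon signed-rank test, as the original analysis protocol prescribes.

## The virtual study

`run_virtual_study()` chains everything per model seed: build phantom →
seeded rigid table placement (±15° yaw, ≤ 5° tilt, ±40 mm translation) →
scene scan from 1400 mm → rough + SOR + fine registration → map motion →
per channel: pose the sleeve near the believed plan (5° / 8 mm start
error), scan it with a zoomed region-of-interest view, cylinder-fit,
align, apply execution noise, insert, and grade against ground truth in
the CT frame (the role the postoperative CT plays physically). The
execution-noise model — Gaussian lateral shift and tilt applied to the
aligned channel — stands in for manual drilling error, which the physical
experiment measures only through its consequences. Any per-model stage
failure is recorded and the study continues.

The default study uses 7 vertebrae × 2 sides × 9 models = 126 wires
(the physical experiment's 124 wires over nine models are not broken down
per model, so the simulation uses a uniform 14 per model). Problem sizes
were chosen for desk-scale runtimes: a 120 × 160 scan grid (~10⁴ rays),
~3 000 skin triangles, an ICP correspondence cap of 5 000 — a nine-model
noiseless study completes in about a minute on one CPU.

In the noiseless limit every stage is exact and the study reproduces the
perfect-placement outcome: 100% of wires at Neo grade 0 with offsets at
machine precision; the acceptance script recomputes exactly this. With
realistic noise switched on (see the README example) offsets rise to a
few tenths of a millimetre while wires remain contained, and mean offsets
increase monotonically with the execution-noise level — a property the
test suite asserts.

## Numerical choices and limitations

* Rigid-transform validation at 1e-9 orthonormality; compositions validated
  at 1e-8 to absorb accumulated rounding.
* Ray-triangle intersection (Möller–Trumbore) with 1e-10 barycentric
  slack; coincident hits on shared edges are deduplicated by parameter
  (1e-9), keeping exterior-ray hit counts even on watertight solids.
* Point-to-mesh distances are exact per triangle (Ericson's closest-point
  construction) with AABB pruning; brute-force oracles in the tests verify
  both to 1e-9.
* STL round-trips are float32-limited; meshes are welded on read by exact
  coordinate match.
* Meshes are faceted: analytic expectations in tests carry an explicit
  sagitta tolerance.
* The phantom is rigid; deformation, bleeding, respiratory motion and
  anatomical variation are out of scope, as is DICOM segmentation (the
  generator supplies meshes directly).
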