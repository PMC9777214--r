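---
title: "Closed-form arm kinematics and shoulder ROM: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-form arm kinematics and shoulder ROM: models, numerics, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armkin)
```

## The kinematic model

The arm is modelled as a serial chain of six revolute joints in the classic
(distal) Denavit–Hartenberg convention, rooted at the sternoclavicular
joint O. Joints 1–2 orient the clavicle (horizontal and vertical rotation),
whose tip is the glenohumeral centre S at distance `l2`; joints 3–5 form
the spherical shoulder complex, with the upper-arm offset `d5` ending at
the elbow centre E; joint 6 is elbow flexion, and the forearm link `l6`
ends at the wrist centre EE, the end effector. Link twists alternate
(−π/2, π/2, −π/2, π/2, −π/2, 0), and only `l2`, `d5`, `l6` are non-zero
constants.

The base frame puts +X lateral toward the instrumented arm, +Z superior,
+Y right-handed. This choice makes the two anatomical branch rules literal
coordinate-sign tests: in a normal posture the clavicle points
upward-oblique (`Zc > 0`) and the shoulder sits lateral to the sternum
(`Xc > 0`).

Angles are radians internally; degrees appear only at reporting
boundaries (ROM tables print one decimal, rounded half away from zero).

## The inverse kinematics and its branch structure

Position stage. The elbow is `E = P − l6·R[,1]`. The shoulder satisfies
three constraints: the sphere `|S| = l2`; the orthogonality plane
`(S − E)·Rz = 0` (the segment E→S is perpendicular to the end-effector
z-axis, a structural property of the chain); and the law-of-cosines plane
`E·S = β`, with `β = (|OE|² − d5² + l2²)/2` fixed by the triangle O–S–E.
Two planes intersect the sphere in at most two points — the two geometric
shoulder candidates. Candidates are screened by the sign rules; if both
pass, the higher (`Zc`-larger) one is taken in stateless use, while along
a trajectory the candidate closest to the previous frame (or to the
measured shoulder centroid, when marker data are available) is kept so the
root choice is continuous. If neither passes, the configuration is an
anatomical violation ("shoulder dislocation"): an error in strict mode, a
flagged `NaN` frame in streaming mode.

Angle stage. Each angle comes from an `atan2` of two elements of a
partial-chain matrix `T0k⁻¹·T06` (rigid-transform inverses, never general
inversion). Three of the pairs are scaled by a neighbouring angle's sine
or cosine, so their raw values are exact only on one half-space:

* the shoulder roll pair is scaled by `sin(theta4)`,
* the pitch pair by `sin(theta5)`,
* the axial pair by `cos(theta6)`.

Rather than assuming a posture, `solve_all()` enumerates all eight
combinations of the three π-flips, evaluates the forward kinematics of
each, and keeps the candidate minimising the pose residual (position
error in mm plus rotation geodesic in rad, weighted 100 mm/rad). Exact
mirror solutions — `(θ3 ± π, −θ4, θ5 ± π)` reproduces any pose exactly —
are broken by continuity with the previous frame, or by the smallest
joint-norm when stateless.

## Numerical choices

* **Rotation distance.** The residual uses
  `2·asin(‖R1 − R2‖F / (2√2))` rather than the trace/acos form: near zero
  the acos form loses half the significant digits (a ≈2·10⁻⁸ rad floor),
  which would mask exact ties between branch candidates.
* **Back-substitution.** The printed elimination divides by individual
  elbow coordinates; when the elbow nears a coordinate axis this loses
  several digits. The solver performs the identical elimination through
  the 2×2 linear system chosen by the largest row-normalised minor of the
  two plane normals, keeping round-trip errors near 10⁻¹¹ mm; the
  textbook-form plane coefficients are still computed and exposed for
  diagnostics.
* **Discriminant.** A negative discriminant within `10⁻⁸·l2²` is clamped
  to tangency. In streaming mode any negative discriminant is clamped and
  flagged: a measured pose can fall epsilon outside the reachable set,
  and the tangency point is its nearest solution.
* **Singularity guards.** `atan2(0, 0)` situations (shoulder on the base
  z-axis, `sin θ4 ≈ 0`, `sin θ5 ≈ 0`, `cos θ6 ≈ 0`) raise typed errors at
  a 10⁻⁹ threshold.
* **Tolerances.** Orthonormality and chain-consistency checks sit at
  10⁻⁹ (10⁻⁶ for measured rotations); an accepted solution must reproduce
  an exact pose to 10⁻⁶.

## The measurement pipeline

Joint centres are the sternal marker (O), the shoulder-triad centroid (S),
and the elbow/wrist pair midpoints (E, EE) — the marker layout is designed
so these coincide with the internal joint centres. Centres are
re-expressed in the base frame: per-frame translation to O, orientation
from a calibration pose (the first second of the recording, assumed near
rest): +X is the horizontal projection of the mean O→S direction, +Z is
laboratory up. A pure yaw offset in the calibration only shifts `theta1`
by a constant and leaves every ROM unchanged.

The end-effector frame is anchored at EE with x = unit(EE − E) — making
the elbow reconstruction exact by construction — and z = unit(x × (S − E)),
which enforces the orthogonality constraint by construction and coincides
with the forward model's end-effector frame on noise-free data.

Marker coordinates are low-pass filtered before analysis (zero-phase
4th-order Butterworth, 6 Hz cutoff, mirror-padded), the standard
pre-treatment of optical capture: voluntary movement here is a ~0.5 Hz
repetition while marker noise is broadband. Unwrapped angle trajectories
are filtered the same way at 3 Hz; a single-harmonic repetition passes
both filters with relative amplitude error below 10⁻⁶, so the noiseless
pipeline stays exact to well under 0.01° while frame-to-frame solver noise
— including the short transients where the closed-form decomposition is
ill-conditioned — is suppressed.

ROM is `max − min` per joint, either globally or (default) per repetition
cycle, averaged; cycles are segmented at rising velocity zero-crossings of
the dominant joint, with segments much shorter than the median merged into
their neighbours. The composite ROM is `θ2 + θ4` for abduction/adduction
(clavicle and shoulder pitch co-rotate) and `θ5` for external/internal
rotation. Cohort statistics use the population SD (divisor n) and
SEM = SD/√n — the convention of the published tables, which the bundled
per-subject records reproduce cell by cell after one-decimal rounding.
Stratum composites are formed from the rounded stratum means, matching the
tables' reporting arithmetic.

Two inconsistencies in the published summary rows are documented rather
than "fixed": the female axial-rotation average prints 106.0 although the
five printed per-subject values average 104.2 (their SD matches the
printed 22.4), and the female height SD/SEM of the rotation table repeat
the male values. The test suite asserts the computed values and excludes
only those cells.

## The synthetic generator

Profiles are raised-cosine cycles (C¹-smooth, zero velocity at cycle
endpoints, so cycle segmentation is unambiguous), 10 repetitions of 2 s at
50 Hz by default. Default amplitudes follow the cohort-average ROM
pattern: (24, −15, 39, 129, 57, 23)° for abduction/adduction and
(4, −3, 8, 8, 109, 24)° for external/internal rotation (the sign encodes
the anatomical direction; clavicle elevation is a negative `theta2`).

Rest offsets are (5, −12, 0, 16, 20, 12)°. They were chosen once, by an
explicit conditioning criterion rather than anatomy alone: every sampled
configuration must satisfy the branch rules with margin, stay away from
the extraction singularities (|sin θ4|, |sin θ5|, |cos θ6| ≳ 0.25), keep
the two geometric shoulder roots ≥ ~13 mm apart along the whole cycle, and
make the first frame unambiguous so a trajectory locks onto the true
branch. Physically this is an arm slightly flexed and abducted at rest —
the posture a therapist would use — rather than hanging exactly at the
singular rest pose.

Markers are placed at fixed body-frame offsets that ride rigidly on their
segments: a 30 mm shoulder triad whose centroid is exactly S, and
symmetric elbow/wrist pairs about E and EE. Isotropic Gaussian noise
(default 0, typically 1 mm in robustness studies) is added per coordinate;
all draws descend from the spec's seed, so identical specs give
bit-identical recordings. An optional rigid world transform exercises the
calibration step.

What the generator does *not* emulate: soft-tissue artefact (markers do
not slide over bone), marker occlusion/gap patterns, non-stationary noise,
within-cycle plane drift across repetitions, and physiological coupling
between clavicle and shoulder beyond independently configured amplitudes.
Passing the synthetic recovery tests therefore demonstrates correctness of
the kinematic chain of computations, not robustness to every artefact of
real capture sessions.

## Problem sizes

The validation suite uses 1000 random branch-valid configurations for the
round trip (pose residual ≤ 10⁻⁶, intermediate identities ≤ 10⁻⁹), 500
instances against a brute-force grid-plus-refinement search on the sphere
(agreement ≤ 10⁻⁴ mm), full ten-repetition recordings at 50 Hz for the
end-to-end checks (noiseless recovery ≤ 0.01°), and 50 seeds at 1 mm
marker noise for the median ROM-error bound (≤ 1°, abduction scenario).

## Known limitations

* During axial humerus rotation the whole arm stays near a single plane,
  and the end-effector pose then constrains the clavicle azimuth (and the
  roll/azimuth split of the shoulder) only weakly: both solution planes
  are nearly tangent to the azimuth direction, so noise is amplified into
  `theta1`/`theta3` transients. This is intrinsic to reconstructing the
  shoulder from the wrist pose alone; the pipeline mitigates it (root
  hints from the shoulder markers, angle-domain filtering) but the
  small-amplitude angles of the rotation movement remain the least
  reliable outputs under noise.
* The branch rules are two sign tests, not a joint-limit model; postures
  whose true shoulder sits below the horizontal are reported as
  violations by design.
* No marker gap-filling or soft-tissue-artefact compensation; gap frames
  are dropped from ROM computation.
* The method is strictly the closed-form construction — there is no
  iterative/least-squares fallback, and no force/torque modelling.
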