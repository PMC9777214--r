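# armkin

Closed-form six degree-of-freedom (6-DOF) arm kinematics and shoulder
range-of-motion (ROM) analysis from optical motion capture.

Shoulder rehabilitation robots must reproduce the biomechanical movement of
the human shoulder. Quantifying that movement — the per-joint rotation
angles and their ROM during standard exercises such as abduction/adduction
and external/internal rotation — requires turning marker trajectories into
joint angles through an explicit kinematic model. `armkin` implements that
model end to end for biomechanists, rehabilitation-robotics engineers and
movement scientists:

* **Forward kinematics.** The clavicle–shoulder–elbow–wrist chain is a
  six-revolute-joint serial chain in the classic Denavit–Hartenberg (DH)
  convention, rooted at the sternoclavicular joint O. Its only non-zero
  link constants are the clavicle length `l2`, the upper-arm offset `d5`
  and the forearm length `l6`; twists alternate (−π/2, π/2, −π/2, π/2,
  −π/2, 0). The positions of the cumulative transforms `T02`, `T05`, `T06`
  are the glenohumeral centre S, the elbow centre E and the wrist centre
  EE (the end effector).

* **Geometric inverse kinematics.** From a measured end-effector pose
  `(R, P)` the elbow is `E = P − l6·R[,1]`. The shoulder S then lies on the
  sphere `|S| = l2`, on the plane through E perpendicular to the
  end-effector z-axis (`(S−E)·Rz = 0`), and on the law-of-cosines plane
  `E·S = β` fixed by the triangle O–S–E. Two planes ∩ sphere give a
  quadratic with two candidate shoulders; anatomy selects among them
  (clavicle upward-oblique, `Zc > 0`; shoulder lateral to the sternum,
  `Xc > 0`), with root continuity along trajectories. The six joint angles
  follow in closed form by `atan2` extraction from partial-chain matrices
  `T0k⁻¹·T06`, with the π-ambiguities of the wrist triple resolved by
  enumerating branch combinations and keeping the one whose forward
  kinematics reproduces the pose.

* **Measurement pipeline.** Wide marker CSV (one marker at the sternum,
  three on the shoulder, two at the elbow, two at the wrist) → low-pass
  filtering → joint centres (centroid / midpoints) → base-frame
  normalization → end-effector pose series → per-frame inverse kinematics
  with QC flags → unwrapped angle trajectories → per-joint ROM (per-cycle
  or global) → composite ROM (`θ2 + θ4` for abduction/adduction, `θ5` for
  external/internal rotation) → sex-stratified cohort statistics
  (population SD, SEM = SD/√n).

* **Synthetic motion.** A generator produces ground-truth raised-cosine
  joint profiles for both exercises (10 repetitions by default) and pushes
  them through the forward model to labelled marker clouds with optional
  isotropic Gaussian noise, so every pipeline stage is testable without
  captured data.

## Worked example

Simulate a noisy ten-repetition abduction/adduction recording, run the
pipeline, and read off the ROM:

```r
library(armkin)

geom <- arm_geometry(l2_mm = 180, d5_mm = 300, l6_mm = 260)
spec <- motion_profile_spec("abduction_adduction", n_reps = 10,
                            sample_rate = 50, marker_noise_sd = 1, seed = 42)
sim <- simulate_motion(spec, geom)
res <- analyze_markers(sim$markers, geom)
res$rom
#> # A tibble: 6 × 2
#>   joint  rom_deg
#>   <chr>    <dbl>
#> 1 theta1    24.1
#> 2 theta2    15.1
#> 3 theta3    39.2
#> 4 theta4   129.
#> 5 theta5    57.1
#> 6 theta6    23.1
composite_rom(res$rom, "abduction_adduction")
#> [1] 144.0775
```

The configured amplitudes were (24, 15, 39, 129, 57, 23)°: with 1 mm of
marker noise every joint's ROM is recovered to a few tenths of a degree,
and the composite abduction ROM (θ2 + θ4) lands at 144.1° against a ground
truth of 144°.

Single poses work too, and round-trip exactly:

```r
th <- c(20, -25, 15, 80, 40, 30) * pi / 180
sol <- solve_all(forward_kinematics(geom, th)$T06, geom)
tidy(sol)        # recovered angles: 20, -25, 15, 80, 40, 30 deg
glance(sol)$fk_residual
#> [1] 1.17e-13
```

Cohort statistics on the bundled ten-subject ROM records reproduce the
published summary rows:

```r
cohort_composites(rom_table_fixtures("abduction_adduction"),
                  "abduction_adduction")
#> # A tibble: 3 × 2
#>   stratum composite_deg
#>   <chr>           <dbl>
#> 1 M                148.0
#> 2 F                138.7
#> 3 all              143.4
```

A thin command-line dispatcher ships in `inst/cli/armkin`
(`armkin simulate | analyze | cohort`).

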