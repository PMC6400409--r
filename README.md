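# screwkin

Six degree-of-freedom kinematic analysis of anatomical joints from rigid
marker-cluster trajectories, built on screw (helical-axis) theory. The
motivating application is the in vitro analysis of a quadruped elbow: a
joint that looks like a hinge but, measured precisely enough, couples its
flexion with a small translation along the flexion axis — a screw joint.
The package is aimed at biomechanists who track bone-fixed markers at
high frequency, digitize the articular surfaces, and want the functional
flexion axis, the five secondary displacement components as functions of
the flexion angle with Student-t error bars, and the geometric gap
between the surface-derived and motion-derived axes.

## What it computes

Given the per-frame pose of the moving bone in the fixed-bone frame, each
sampling step is decomposed into a rotation φᵢ about a unit axis **n**ᵢ
plus a translation dᵢ along it. The Rodrigues parameters (unit-quaternion
components) of the incremental rotation matrix give

    S = ½√(1 + a₁₁ + a₂₂ + a₃₃),  L = (a₃₂−a₂₃)/4S,
    M = (a₁₃−a₃₁)/4S,             N = (a₂₁−a₁₂)/4S,
    φ = 2 arccos S,               n = (L, M, N)/sin(φ/2).

Origin and angular velocities come from the five-point stencil
ẋᵢ = (xᵢ₋₂ − 8xᵢ₋₁ + 8xᵢ₊₁ − xᵢ₊₂)/(12 dt), the instantaneous axis point
is **A**ᵢ = **O**ᵢ + (**ω**ᵢ × **V**ᵢ)/(**ω**ᵢ·**ω**ᵢ), and the axial
increment is dᵢ = (**O**ᵢ₊₁ − **O**ᵢ)·**n**ᵢ₊₁. The mean flexion axis,
the best-fit sphere of the humeral head and the epicondyle landmarks
define the anatomical joint frame (U_Z along the axis); displacements are
decomposed there as an intrinsic Z-Y-X Tait-Bryan cascade (flexion R_Z
first) plus translations (T_X, T_Y, T_Z), aggregated across trials on a
flexion grid with half-widths t₀.₉₇₅,ₙ₋₁·s/√n.

A first-class synthetic module generates the whole experiment — screw
motion, noisy marker trajectories, digitized surfaces with landmarks —
from planted ground truth, so every stage is testable by parameter
recovery.

## Worked example

Simulate the intact-specimen experiment (25 repeated measurements of a
0→91° flexion gesture at 100 Hz, marker noise 0.012 mm, surface noise
0.02 mm) and run the full analysis:

```r
library(screwkin)
sc <- make_scenario("fresh", seed = 1)
trials <- lapply(1:25, function(j) scenario_trial(sc, 100 + j))
res <- analyze_experiment(trials, sc$bones,
                          sc$scene$geom_fixed, sc$scene$geom_moving)
res
#> Joint kinematic analysis
#> Mean flexion axis: n_m = (0.15073, -0.08044, 0.98530), A_m = (26.847, -18.318, -5.602) mm, 99925 steps
#>   excluded screw steps: 3 of 4000
#> Axis comparison: in-plane offset 1.308 mm, angular difference 5.107 deg
#>   significant DoFs: T_Z
res$curves
#> DoF curves: 92 grid points (0 to 91 deg flexion), 25 trials, t = 2.064 (alpha = 0.05)
#>   R_X: -0.01262 to 0.01152 deg
#>   R_Y: -0.0133 to 0.00886 deg
#>   T_X: -0.01191 to 0.009597 mm
#>   T_Y: -0.01143 to 0.00671 mm
#>   T_Z: -0.003082 to 0.4607 mm
```

Reading the output: the recovered mean flexion axis matches the planted
axis direction to ~0.01°; of the five secondary displacement components
only the medial-lateral translation T_Z (which ramps to ~0.46 mm at full
flexion) rises above the 0.012 mm measurement uncertainty — the joint
behaves as a screw, not a hinge — and the best-fit trochlea cylinder axis
sits 1.308 mm from, and 5.107° tilted against, the motion-derived axis
(the scenario plants 1.31 mm and 5.11°). The first and last two frames of
each gesture are excluded because the five-point stencil has no support
there.

File-based workflows use `simulate_experiment()` /
`analyze_dir()` (TRC + CSV markers, ascii PLY surfaces, JSON landmarks
and reports); `export_coupling_table()` writes the flexion→T_Z coupling
for downstream musculoskeletal tools.

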