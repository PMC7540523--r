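---
title: "Methods: automated mitral valve vortex ring extraction"
author: "mvring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated mitral valve vortex ring extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During each diastolic filling wave, blood entering the left ventricle (LV)
through the mitral valve rolls up into a toroidal vortex ring at the
leaflet tips — once during early filling (E wave) and once during atrial
contraction (A wave), with dissolution during the low-flow diastasis in
between. The ring's strength, energy and geometry are candidate markers of
diastolic function. 4D-flow MRI measures all three velocity components in
every voxel over the cardiac cycle (here ~30 frames at anisotropic spatial
resolution, e.g. 1.8 × 2.5 × 4 mm³), which makes automated, observer-free
extraction of the ring possible. `mvring` implements that extraction in
four steps, plus a ground-truthed flow phantom and segmentation-robustness
experiments.

Internally all physics is SI (m, s, m/s, s⁻¹, s⁻², J); geometry and
reporting use the field's conventional units (mm, mL, mJ, J/m³, degrees).
Voxel indices are 1-based in R with voxel-center physical coordinates
`origin + (index − 1) · spacing`; bounding boxes are half-open in 0-based
indices.

## Step 1 — divergence-free velocity (`divergenceFreePart`)

A smooth velocity field decomposes uniquely into a rotation-free, a
divergence-free and a harmonic part. Only the divergence-free part `r`
carries the rotational information needed for vortex detection; measured
fields additionally contain non-solenoidal contamination (residual phase
offsets, noise) that this step removes. `r` is represented as the curl of
a vector potential Ψ, which turns the decomposition into the curl–curl
system `∇×∇×Ψ = ∇×v` with `Ψ = 0` clamped on the boundary shell of the LV
bounding box — equivalent to requiring `r` tangential to the box.

Discretization: second-order central differences, with second-order
one-sided stencils on the box faces; the same stencils are used by every
differential operator in the package, so `r` is *exactly* the discrete
curl of the returned Ψ. The discrete operator is rank-deficient (discrete
gradients lie in its null space — the reason a plain linear solve cannot
be used), so the system is solved by minimum-norm least squares: LSQR
started from zero, which converges to the minimum-norm solution. The
solver stops on the relative residual (consistent systems) or on the
normal-equation optimality measure `‖Aᵀr‖/(‖A‖‖r‖)` (noisy, inconsistent
systems); non-convergence within the iteration cap is an error that
reports the achieved residual. The curl–curl matrix is assembled once per
box geometry and reused across frames; frames are solved independently.

Tolerances: `solveVectorPotential()` defaults to 1e-8. The pipeline
(`mvringConfig()$hodgeTol`) uses 1e-6, far below the spatial
discretization error of the data (percent scale), at roughly 650 LSQR
iterations per frame on the phantom bounding box.

One caveat documented deliberately: the harmonic part of the *true* flow
(through-plane flow across the box faces) is removed together with the
contamination. This component is smooth and low-gradient, so Q and the
ring geometry are essentially unaffected, but `r` should not be read as
"the true velocity" near the box faces.

## Step 2 — Q analysis (`qField`, `frameThresholds`, candidates)

The Q criterion marks a voxel as vortical when rotation dominates strain:
`Q = ½(‖Ω‖² − ‖S‖²) > 0`, with Ω and S the antisymmetric and symmetric
parts of the velocity gradient of the divergence-free field. Q is
Galilean-invariant and `ω²` for rigid rotation at rate ω.

The raw Q series is filtered — spatial Gaussian, then a median filter,
then temporal Gaussian smoothing with cyclic boundary (the cardiac cycle
is periodic) — to suppress noise and short-lived structures, and the LV
masks are applied. Defaults (σ = 1 voxel per axis, 3³ median window,
σ = 1 frame) are the smallest standard kernels that serve that purpose;
all are configurable.

Frame-specific thresholds follow the cross-frame location rule: record
the argmax location of masked Q in every frame n, then threshold frame i
at the mean of `Q_i` over all N locations. This adapts the threshold to
each frame's vortex strength while anchoring it to the locations where
strong vortices live at some point in the cycle. A frame whose masked Q
is identically zero contributes its first mask voxel (documented
convention).

**Vortex-frame window.** Analysis is restricted to the diastolic-to-early-
systolic window identified from the curve of per-frame Q maxima. Frames
with `maxCurve ≥ κ_w · mean(thresholds)` (default κ_w = 0.5) are *active*;
the window is the shortest cyclically contiguous interval covering all
active frames — the complement of the largest cyclic gap between them.
This deliberately *bridges* diastasis: with a biphasic inflow the active
frames form two bursts (E and A), and the window must span both so that
the A ring is examined at all; a rule that kept only one contiguous
above-threshold run would truncate the window at the end of the E burst
whenever diastasis activity drops to baseline. The two peak frames are
the two largest local maxima of the curve inside the window separated by
at least 3 frames (a single local maximum serves as both).

**Candidates.** Thresholding typically yields several 26-connected regions
(26-connectivity because vortex shells are thin and diagonal-connected at
4 mm slices; components under 5 voxels are below the smoothing scale and
dropped). To score which regions belong to the MV ring, principal
component analysis of the thresholded Q fields over the window condenses
the 4D information into the spatial map `w1` of the first component
(per-voxel temporal centering; sign fixed to be non-negative at the
global Q maximum). Each region's candidate factor is the w1 sum over its
voxels divided by `d_max`, its maximal LV-long-axis distance to the w1
maximum (floored at 1 mm — the ratio is singular for a region sitting on
the maximum). Regions with `d_max ≥ 2 × min d_max` are discarded and the
top two by factor are kept.

## Step 3 — core tracing and tracking (`traceCore`, `trackCores`)

From the Q maximum of a candidate, the core line grows by a
predictor–corrector scheme: the predictor steps along the locally
interpolated vorticity direction (vorticity of the divergence-free field
— analytically identical to the full field's curl, discretely smoother);
the corrector maximizes interpolated Q on the plane perpendicular to the
vorticity at the predictor, by compass pattern search (mesh from 1 × min
spacing contracting ×0.5 to 0.1 × min spacing, confined to a 2 × max
spacing radius so the corrector cannot jump to a neighbouring vortex).
The corrector only accepts improvements, so corrector Q never falls below
predictor Q.

Stop rules: arriving back at the start (closed ring), getting stuck
(displacement below 0.1 × step, or revisiting an earlier point), reaching
non-positive Q, or the step cap. If the forward line does not close, a
backward trace runs with the same rules and may close by fusing with the
forward line. Closed = torus; an open merged line with total turning
≥ 150° = U; two open lines with mutually adjacent endpoint pairs
(≤ 2 × max spacing) and joint turning ≥ 150° = bracket; else none.

Two numerical choices matter on anisotropic grids and are this package's
own:

* **Closure tolerance = half the voxel diagonal** (2.5 mm at
  1.8 × 2.5 × 4 mm), tested against the segment travelled in each step,
  with the seed first refined onto the sub-voxel core by one corrector
  application. Trilinearly interpolated Q has kinks at voxel boundaries,
  so the corrected core line wobbles at the voxel scale between laps; a
  closure tolerance below that scale (e.g. one step length) never fires
  and produces multi-lap "closed" cores.
* **Polyline regularization**: four passes of a 1-2-1 moving average
  (cyclic for closed lines, endpoints fixed for open ones), reverting any
  point that smoothing would push out of the vortex (interpolated
  Q ≤ 0). This damps the same voxel-scale corrector jitter; without it
  the traced circumference of a circular ring overshoots 2πR by a factor
  ~2 and consecutive points can jump farther than twice the step.

Temporal tracking starts at the two peak frames (membership there
requires a ring-like shape) and proceeds E-peak → backward to the window
start and forward up to the inter-peak minimum of the max-Q curve, then
A-peak → forward to the window end and backward down to the minimum.
With two traced cores that are not jointly a bracket, the one nearer the
previous frame's core centroid is kept. Membership propagates when the
previous visited frame held a ring and both the centroid displacement
(≤ 10 mm) and the relative major-axis change (≤ 50%) are small; the
thresholds operationalize "small" and are configurable. Membership
periods are therefore contiguous within each of the E and A iteration
ranges, and at most one MV core exists per frame.

## Step 4 — region growing (`seedPoints`, `growRegion`, `pruneRegion`)

Streamlines of the frame-frozen divergence-free field are seeded at the
core voxels and their 26-neighbourhoods (clipped to the LV mask) and
integrated in both directions with RK4 on trilinear interpolation (step
0.5 × min spacing, 1000 steps per direction). Every voxel entered is part
of the ring region; a streamline ends on non-positive Q, on leaving the
mask, or at the step cap. Outlier branches are pruned by iteratively
removing voxels with fewer than eight occupied 26-neighbours
(simultaneous sweeps, hence order-independent; the 26-neighbourhood is
assumed since under 6-connectivity "eight neighbours" would be
unsatisfiable).

Termination uses the *unfiltered* Q of the divergence-free field, while
thresholds and candidates use the filtered Q. The spatial smoothing that
stabilizes thresholding also inflates the Q > 0 domain by about one
kernel width — a full slice along the 4 mm axis — which on the phantom
doubles the ring-region volume relative to the analytic Q > 0 torus. The
physical extent of the ring is a property of the field, not of the
filter, so the region (and the volume parameter derived from it) follows
the unfiltered criterion.

## Parameters (`parameterTimecourse`)

Per MV-ring frame: region volume (voxel count × voxel volume, mL);
maximum and mean vorticity over the region, from the *un-decomposed*
velocity field by central differences, with the 95th percentile (linear
interpolation between order statistics) as the outlier-robust maximum;
absolute kinetic energy `Σ ½ ρ |v|² dV` with blood density
ρ = 1060 kg/m³ (mJ) and its volume-normalized counterpart (J/m³), also
from the full field — consistent with the vorticity convention; the angle
between the total-least-squares plane fit of the core and the LV long
axis, folded into [0°, 90°] (90° = ring lies in a short-axis plane); and
the circularity index, the ratio of the second-largest to largest
principal axis length of an ellipsoid fitted to the core points (axis
length = 2 × max |projection|, lengths sorted — with jittery points the
range along the second principal direction can exceed that along the
first). Peak summaries are per-membership-period maxima (E and A). The
LV long axis comes from the configuration, or else from the first
principal axis of the end-diastolic mask voxels, oriented from the wider
(basal) end to the apex.

## The flow phantom (`biphasicPhantom`)

The phantom emulates the study conditions at acquisition scale: a
64 × 64 × 40 grid at 1.8 × 2.5 × 4 mm³, 30 frames; an ellipsoidal LV of
semi-axes 22.5 × 22.5 × 42 mm (45 mm lateral diameter, 84 mm base–apex
length — normal adult dimensions); a vortex ring of radius 16 mm
(mitral-annulus scale) with a 4 mm Gaussian (Lamb–Oseen-like) core and
circulation 0.01 m²/s, placed at the LV center with its plane
perpendicular to the long axis. The velocity is the Biot–Savart field of
a 128-segment polygonal filament with the 3D Gaussian smoothing kernel
(σ = a/√2, giving the vorticity profile `Γ/(πa²)·exp(−ρ²/a²)` and
on-axis velocity → Γ/2R in the thin-core limit); it is analytically
divergence-free. The lateral wall clearance of the ring tube is ~1 voxel,
as for a real mitral annulus — so mask erosion genuinely cuts into the
ring region, which is what the segmentation-sensitivity experiments
probe.

The amplitude curve is biphasic: raised-sine ramps inside the E window
(frames 3–8, peak 1.0) and A window (frames 14–19, peak 0.6, the normal
E > A pattern), exactly zero in diastasis and systole; presence truth is
`amplitude > 0`. Contamination is `gradAmp` (default 0.05 m/s) times the
discrete gradient of a smoothed random scalar field — rotation-free *by
construction under the package's own stencils*, so the clean ring field
is exactly the divergence-free truth — plus iid Gaussian noise (default
0.02 m/s, a few percent of the ~0.3 m/s peak inflow velocity, typical
4D-flow noise). The region truth is the largest connected component of
{Q > 0} of the clean field inside the mask; Q > 0 is invariant to
positive amplitude scaling, so one region serves all present frames.

What the phantom does *not* emulate: chamber anatomy and moving walls,
valve leaflets, ring translation/deformation over the cycle, turbulence,
k-space/phase noise physics, and phase wraps. Passing the phantom suite
therefore demonstrates the correctness of the numerics and the logic of
detection/tracking under controlled contamination — not clinical
performance on patient data.

## Validation and experiments

`runExperiment()` re-runs the extraction under perturbed masks — every
k-th short-axis slice retained with nearest-slice fill (ties toward the
base), a static end-diastolic mask, or one-voxel 6-connected
erosion/dilation — and reports presence agreement (Cohen's κ, with
κ ≡ 1 when both raters agree perfectly under a degenerate margin and 0
otherwise), mean core Dice (polylines rasterized to voxels entered, then
dilated by one 26-shell so sub-voxel offsets do not dominate) and region
Dice over common ring frames, and percentage errors of the E/A peak
parameters.

## Problem sizes and runtimes

The test suite exercises the full acquisition-scale phantom
(64 × 64 × 40 × 30) once and shares that extraction across the
end-to-end, robustness and determinism checks (~5 minutes on one CPU);
unit tests use analytic rings on 32³–64³ grids and small algebraic
fixtures. `scripts/acceptance.R` regenerates the phantom from its `--seed`
and recomputes every reported quantity from scratch (~5 minutes).

## Known limitations

* The harmonic (through-flux) component of the true flow is removed with
  the contamination; quantities computed from `r` near the box faces are
  biased accordingly (Q and the ring are interior and unaffected in
  practice).
* The discrete curl underestimates the core-center vorticity of a
  Gaussian core by ~19% when the core radius is 2 voxels (~10% at 3,
  ~6% at 4); with 4 mm slices and a 4 mm core this mainly affects peak —
  not mean — vorticity.
* Membership tracking assumes one dominant ring per filling wave; the
  two-candidate/bracket rule handles a split ring but not more complex
  pinch-off topologies.
* A vortex window is only defined when some frame activity clears
  κ_w × mean threshold; an all-quiet series returns an empty result with
  a warning rather than an error.
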