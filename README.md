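# mvring

Automated extraction and quantification of the **mitral valve (MV) vortex
ring** from 4D-flow MRI.

During diastolic filling, blood entering the left ventricle (LV) through
the mitral valve rolls up into a toroidal vortex ring at the leaflet tips
— once during early filling (E wave) and once during atrial contraction
(A wave). Its strength, energy and geometry are candidate markers of
diastolic (dys)function, but reading them off velocity data by eye is slow
and observer-dependent. `mvring` turns a time-resolved three-directional
velocity series plus a per-frame LV segmentation into per-frame ring
detections, core lines, ring regions and six quantitative parameters —
fully automatically. It is aimed at cardiovascular MR researchers working
with 4D-flow acquisitions, and ships a ground-truthed analytic flow
phantom so every stage can be validated without patient data.

## Method

Given velocity frames `v` and LV masks, the pipeline runs four steps in a
bounding box around the LV:

1. **Divergence-free field.** By the Helmholtz–Hodge decomposition,
   `v = d + r + h` with `∇×d = 0`, `∇·r = 0`. The rotational part `r` is
   written as `r = ∇×Ψ` and obtained from the curl–curl system
   `∇×∇×Ψ = ∇×v`, `Ψ|∂Ω = 0` (tangential `r`), discretized with
   second-order finite differences and solved by minimum-norm least
   squares (LSQR; the discrete operator is rank-deficient — gradients lie
   in its null space).
2. **Vortex candidates.** The Q criterion, `Q = ½(‖Ω‖² − ‖S‖²)` with spin
   tensor Ω and strain-rate tensor S of `r`, marks vortical voxels
   (`Q > 0`). After Gaussian, median and cyclic temporal filtering and
   masking, frame-specific thresholds `thr_i = (1/N) Σ_n Q_i(r_n^max)`
   are applied, the diastolic-to-early-systolic *vortex frames* are found
   from the max-Q time curve, and connected super-threshold regions are
   scored by `f_c = (Σ_m w1(m)) / d_max`, where `w1` is the first
   principal component of the thresholded Q series over time and `d_max`
   the region's long-axis distance to the `w1` maximum; the top two
   regions become candidates.
3. **Core line and tracking.** From each candidate's Q maximum a
   predictor–corrector scheme traces the core: predictor along the local
   vorticity direction, corrector to the pattern-search Q maximum on the
   perpendicular plane; stopping on closure (torus), getting stuck, or
   `Q ≤ 0`, with U- and bracket-shape tests for open lines. Tracking runs
   from the two peaks of the max-Q curve outwards; membership propagates
   while the centroid displacement and major-axis change stay small.
4. **Ring region and parameters.** Streamlines of `r`, seeded at the core
   and its neighbourhood, mark the ring region until they reach `Q ≤ 0`;
   thin branches are pruned (voxels with < 8 of 26 neighbours, to a
   fixpoint). Per ring frame the package reports volume, 95th-percentile
   and mean vorticity magnitude (from the un-decomposed field), absolute
   and relative kinetic energy (ρ = 1060 kg/m³), the angle between the
   core plane and the LV long axis, and the circularity index
   (short/long fitted ellipsoid axis).

Validation utilities reproduce segmentation-sensitivity experiments
(slice subsampling `2d…6d`, static end-diastolic, one-voxel
eroded/dilated masks) and score agreement with Cohen's κ and Dice
coefficients. See the methods vignette
(`vignettes/mvring-methods.Rmd`) for assumptions, tunables and numerical
choices.

## Worked example

Run the full pipeline on the built-in biphasic vortex-ring phantom
(64 × 64 × 40 voxels at 1.8 × 2.5 × 4 mm³, 30 frames, E ring frames 3–8,
A ring frames 14–19, noise and gradient contamination added):

```r
library(mvring)
ph  <- biphasicPhantom(seed = 1)
res <- extractVortexRing(ph$velocity, ph$masks, mvringConfig())
res
#> MVRingResult: MV ring present in 12/30 frames (2 periods)
#> QSeries: 30 frames on box; vortex window 2..19; peaks 5, 17

subset(ringParams(res), present,
       select = c(frame, vol_mL, vort_max_s1, vort_mean_s1,
                  ekin_abs_mJ, alpha_deg, ci))
#>  frame vol_mL vort_max_s1 vort_mean_s1 ekin_abs_mJ alpha_deg    ci
#>      3   7.78        65.3         41.8      0.0551      87.6 0.958
#>      4   7.49       108.0         73.1      0.1624      89.5 0.946
#>      5   7.16       130.8         91.8      0.2340      89.1 0.967
#>      6   7.27       133.3         92.1      0.2409      87.6 0.942
#>      7   7.47       107.4         72.4      0.1564      88.1 0.968
#>      8   7.99        62.2         40.8      0.0531      87.8 0.974
#>     14   7.34        44.2         28.4      0.0222      87.6 0.997
#>     15   7.96        68.0         44.2      0.0652      89.2 0.963
#>     16   7.58        82.2         54.9      0.0910      88.2 0.956
#>     17   7.42        83.4         55.9      0.0908      87.5 0.978
#>     18   7.74        68.8         44.4      0.0631      89.3 0.931
#>     19   7.42        44.9         28.7      0.0227      89.2 0.878
```

The detector finds exactly the two seeded filling-wave periods (frames
3–8 and 14–19). The ring volume (~7–8 mL) matches the analytic `Q > 0`
torus of the phantom (7.2 mL); mean vorticity peaks at the E-wave
amplitude maximum and is ~0.6× as large for the weaker A ring; the core
plane stays within a few degrees of the short-axis orientation
(`alpha ≈ 90°`) and the ring is nearly circular (`ci > 0.93` except at
the fading A-ring tail). Agreement statistics come from the same
package:

```r
cohenKappa(confusionMatrix2x2(a = 301, b = 15, c = 54, d = 230))
#> [1] 0.7676543
```

A command-line front end is installed with the package
(`exec/mvring`): `mvring extract`, `mvring simulate`,
`mvring experiment --condition {2d..6d,end-dia,erode,dilate}` and
`mvring score` wrap the same functions for shell use, reading NIfTI
volumes and a YAML configuration.

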