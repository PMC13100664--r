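---
title: "Methods: orbit planning, sharpness-driven focus stacking, and scaled measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orbit planning, sharpness-driven focus stacking, and scaled measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

orbitstack is a hardware-free implementation of the computational side of a
specimen-stationary macro-photogrammetry rig: the camera orbits a pinned
specimen on six machine axes, takes a focus stack at every viewpoint, fuses
each stack into an extended depth-of-field (EDOF) image, and the resulting
photo set is reconstructed into a 3D model by external structure-from-motion
tools. This vignette documents the models, parameters and numerical choices
behind each stage, and what the synthetic tests do and do not demonstrate
about real acquisitions.

## Kinematic model

The rig is modelled as three subsystems: a translational stage (X, Y, Z, mm),
a rotational stage controlling the camera's azimuth A and elevation B
(degrees), and a stacking stage C (mm) that translates the whole
camera-lens assembly approximately along the optical axis. Default travel
limits are 800 mm per translational axis, continuous rotation modulo 360° for
A, ±45° for B, and 100 mm of usable C travel; all limits are configurable via
`axis_limits()`.

The world frame is right-handed with Z vertical, so the constant-Z "layers"
used to densify viewpoint coverage are vertical shifts. Two conventions are
fixed here because no standard exists for them:

* **Azimuth zero**: A is the heading of the camera's *view direction*,
  measured counter-clockwise from +X. A camera on the +X side of the aiming
  point looking back at it therefore has A = 180°. B is the camera's angle
  above the horizontal plane through the aiming point (camera straight above
  → B = 90°, unreachable with the default ±45° tilt).
* **C sign**: positive C moves the camera *toward* the specimen (decreasing
  working distance). `rig_geometry("away")` flips this.

`plan_orbit()` places rings of equally spaced azimuths at the requested
elevations on a sphere about the aiming point and converts each camera pose
to machine coordinates. Unreachable poses fail loudly by default;
`skip_unreachable = TRUE` drops them with a warning, because silently losing
viewpoints degrades photogrammetric overlap in ways that only surface much
later, at reconstruction time. Forward and inverse kinematics are exact
inverses; the suite verifies the round trip to 1e-9 on 1000 random reachable
poses.

Sequences are exchanged as CSV with columns `x,y,z,a,b`, a header row, `.`
decimal marks and six printed decimals; row order defines the 0-based
sequence index. The stacking axis is driven at acquisition time and is not
part of the file. The published acquisition geometry this package mirrors
used a manually taught base path replicated at three constant Z offsets for a
total of 488 viewpoints; whether that base path had one or two rings is not
derivable from the viewpoint count alone, so the worked examples here use a
61-azimuth × 2-elevation base layer (122 poses → 488 after three offsets).
`replicate_with_z_offsets()` is parametric in the offset list, so any layer
structure is expressible.

## The digital-twin camera

The simulator exists so acquisition logic can be exercised without hardware;
it is intentionally the simplest model with the right monotonicities, not a
physically calibrated camera.

* **Fixed magnification.** Because the physical rig focuses by translating
  the whole camera rather than refocusing the lens, magnification is constant
  within a stack. The twin therefore applies no per-frame scale change or
  lateral shift, which is also what justifies fusing stacks without
  inter-frame registration. A `lateral_offset_px` argument injects
  translational jitter on demand; the suite uses it to show the seam metric
  degrading when the fixed-framing assumption is broken.
* **Sampling arithmetic.** Object-space sampling is pixel pitch divided by
  magnification (`object_space_sampling(4.1, 2)` = 2.05 µm/px). The default
  simulated sensor is 512 × 341 — the 3:2 aspect of a 5472 × 3648 sensor at
  ~1/10.7 scale — with a `pixel_binning` factor entering the mm-per-pixel
  conversion so the scaled sensor sees the same field of view.
* **Defocus.** Blur radius grows linearly with distance from the focal
  plane, `radius = blur_gain_px_per_mm × |offset|` (default gain 3 px/mm);
  the focal plane sits at `focus_distance_mm − c_pos_mm` along the optical
  axis. Focus stacking only requires blur to grow monotonically off the
  focal plane, which this model guarantees by construction; thick-lens
  effects are deliberately out of scope.
* **Rendering.** Specimen surface samples are projected orthographically at
  fixed scale, grouped into depth slabs sharing one blur width (quantized on
  a ladder that is fine near focus and geometric far from it, capped at
  σ = 40 px), blurred with a three-pass box approximation to a Gaussian, and
  composited far-to-near with density-based opacity over a uniform
  background. Rendering is pure: identical inputs give bit-identical frames.

`generate_specimen()` builds a reproducible dome-shaped test subject with
exactly the requested lateral size and depth extent. Its intensity texture is
a soft-thresholded sum of 24 random plane waves with wavelengths of
0.08-0.5 mm, giving spatially coherent blotches that produce dense edges in
focus and wash out quickly under defocus — the property the autofocus
criterion needs. The default background (0.45) is close to the texture mean,
as it would be for a specimen photographed against a neutral card, so a
heavily defocused specimen fades into the background instead of leaving a
permanent high-contrast outline. Each specimen carries named landmark pairs
with exactly known distances, including a `mount_bar` pair standing in for
caliper-marked points on a physical mount.

What the twin does **not** emulate: real surface reflectance (gloss,
translucency), illumination structure, occlusion-correct perspective, sensor
noise and vibration. Tests passing on the twin therefore demonstrate the
correctness of the *pipeline logic* — termination rules, fusion argmax,
depth indexing, scale arithmetic — not performance on difficult real
specimens.

## Edge-based sharpness and stack termination

A frame's sharpness score is the fraction of its pixels on detected edges.
Detection is Canny-style on the luminance image: optional Gaussian
pre-smoothing (σ = 1 px default), Sobel gradient scaled so a full-contrast
step edge has magnitude 0.5, non-maximum suppression along the quantized
gradient direction, then hysteresis linking with low/high thresholds of
0.0005 and 0.002 in normalized intensity units (defaults; both
configurable). Two implementation details matter:

* The Sobel gradient is computed with exact shifted-matrix arithmetic rather
  than FFT convolution, and suppression keeps plateau ties (with a 1e-9
  tolerance), so an ideal step edge survives on both of its gradient columns
  and the score is exactly reproducible by a brute-force gradient scan.
* Normalizing by pixel count (rather than reporting a raw edge count) makes
  the score comparable across frame sizes.

The thinning step is what makes the score discriminate focus: an in-focus
textured surface contributes many ridges, while a defocused boundary
collapses toward a single faint ridge and, against a matched background,
eventually below the hysteresis thresholds.

The **focus criterion** — the score above which a frame counts as in focus —
is calibrated empirically, as on the physical rig: `calibrate_criterion()`
sets it to a safety margin (default 2×) times the highest score observed on
background-only pilot frames, and refuses calibrations where that threshold
reaches the weakest in-focus pilot. In twin sessions the natural background
pilots are far-defocused frames of the same scene (everything that remains
when no specimen structure is resolvable); a margin of 1.5-2 separates them
cleanly from in-focus scores in all shipped configurations.

`acquire_stack()` steps C from `c_start_mm` in `c_step_mm` increments and
stops as soon as `stop_after` consecutive frames score below the criterion.
The count is exactly 10 by default — the published behaviour is "about ten",
and a concrete default is needed; it is exposed as a parameter. The
consecutive-below counter resets on any in-focus frame, so a brief dip never
terminates a stack early (verified by an interleaved trace test). Trailing
below-criterion frames are kept in the stack and flagged: they cost nothing
and give the fuser a conservative margin beyond the focal region. If no
frame is ever in focus the loop stops after `stop_after` frames, and a
`max_frames` cap (500) guarantees termination, recording a truncation flag
if focus was still being seen. One consequence of the degenerate rule: the
start position should be chosen within `stop_after` steps of the first
in-focus plane, or the stack ends before reaching it; session examples
start the sweep 2-4 steps before the focal band.

## EDOF fusion and shape-from-focus

Per-pixel focus evidence is the variance of the Laplacian response in a
square window (default 9 px) — standard shape-from-focus practice. Fusion
selects, per pixel, the frame with maximal local sharpness; ties break to
the lowest frame index so results are platform-independent. The resulting
depth-index map is cleaned with a 3 × 3 majority filter (ties again to the
lowest index) to suppress salt-and-pepper index noise. Pixels whose best
evidence falls below a floor (1e-6) are untextured background: they take the
median frame's value and the sentinel index −1 rather than amplifying noise
into spurious depth. `depth_from_stack()` maps depth indices to
stacking-axis positions, giving coarse depth at one-C-step resolution; on a
two-plate twin scene it recovers a 4 mm separation within the 0.5 mm step.

No multi-resolution blending is performed; hard seams at focus boundaries
are acceptable at desk scale and noted as an extension point. No inter-frame
registration is performed either (see the fixed-magnification rationale
above).

## Scaling and measurement

Reconstruction itself is external; this package consumes reconstructed
models (ASCII PLY, minimal OBJ) in arbitrary units. A single scalar scale is
computed from one two-landmark constraint — `known_distance_mm` divided by
the landmarks' model-space separation — and applied isotropically. One
distance determines exactly one scalar; estimating similarity transforms
from multiple constraints is deliberately out of scope. Scale-then-measure
recovers the constraint distance to floating-point precision
(self-consistency), and on noiseless twin models every other landmark
distance is recovered exactly.

Validation statistics follow the conventional definitions: per-record signed
absolute error `model − reference` (mm), relative error
`|model − reference| / reference × 100` (%), and summaries MAPE (unweighted
mean of relative errors), MAE and RMSE, reported in both mm and µm.
RMSE ≥ MAE holds for every record set, with equality when all absolute
errors share one magnitude. Because the per-distance raw measurements behind
the published hardware validation are not available, the suite substitutes a
parameter-recovery experiment: landmark distances on a noise-perturbed twin
model, scaled through one landmark pair, show MAPE growing monotonically
with injected point noise and vanishing as the noise does.

## Sessions

`run_session()` visits viewpoints in file order through a simulated motion
controller that refuses out-of-limit moves (such a refusal marks the
viewpoint `failed` with the violation text and the session continues),
acquires and optionally fuses each stack, and maintains a JSON manifest.
Sessions are resumable: completed viewpoints are never re-acquired. The
manifest is deterministic given the inputs — wall-clock timestamps live only
in the append-only `log.txt` — so two runs with the same configuration
produce identical manifests and bit-identical EDOF files, which the suite
checks byte-for-byte. Session layout:

```
session/
  config.yaml  sequence.csv  manifest.json  log.txt
  000/ frame_000.png ... stack.json
  edof/ 000.tif 000.png 000_depth_index.tif 000_depth_mm.tif 000_depth.json
```

Depth maps in mm are stored as 32-bit float TIFF normalized to [0, 1] with a
JSON sidecar carrying the offset/scale (the TIFF writer only preserves that
range losslessly); depth-index maps are 16-bit TIFF holding index + 1 with 0
as the no-evidence sentinel.

## Problem sizes and test design

The shipped tests run entire sessions at reduced frame sizes (96 × 64 and
128 × 96) where the geometry is unchanged and each frame renders in
milliseconds, plus one four-viewpoint session at the full simulated
resolution of 512 × 341 with roughly 30-45 frames per stack, which completes
in well under five minutes on a single core. Stack lengths in that
configuration fall inside the 20-70 raw-frames-per-stack band expected for
specimens whose depth spans many depth-of-field slabs. Generator defaults
(10 mm specimen, 5 mm depth, 150 mm orbit radius, 0.5 mm C steps, blur gain
3 px/mm) were chosen once to represent a typical pinned-insect scan at desk
scale and are not tuned per test.

## Known limitations

* The renderer's opacity model is approximate; silhouette edges of a
  heavily defocused specimen can retain faint ridges, which is why criterion
  calibration should use far-defocused pilots rather than assume a zero
  background score.
* The linear blur model has no depth-of-field plateau; the effective
  in-focus slab thickness is set implicitly by the blur gain, the texture
  wavelengths and the criterion.
* Fusion produces hard seams and no halo suppression; depth maps are
  quantized to the C step.
* PLY support is ASCII-only; binary PLY must be converted externally.
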