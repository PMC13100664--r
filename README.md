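# orbitstack

Hardware-free toolkit for the computational pipeline of specimen-stationary
macro-photogrammetry rigs: robots that orbit a camera around a pinned insect
(or other small specimen), take a focus stack at every viewpoint, fuse each
stack into an extended depth-of-field (EDOF) image, and hand the photo set to
external structure-from-motion software for 3D reconstruction.

orbitstack implements everything around the hardware:

* **Orbit planning** in six machine axes — X/Y/Z translation, azimuth (A) and
  elevation (B) of the view direction, and a dedicated focus-stacking axis
  (C) along the optical axis. Sequences are validated against axis travel
  limits (defaults: 800 mm per translational axis, continuous A, ±45° B,
  100 mm usable C) and exchanged as CSV files whose row order defines the
  0-based viewpoint index. Base paths can be replicated at constant vertical
  offsets to densify coverage, e.g. 122 poses × (1 + 3 offsets) = 488
  viewpoints.
* **A thin-lens digital twin** that renders defocus-blurred frames of a
  synthetic textured specimen at fixed magnification, so acquisition logic
  runs with no camera attached. Object-space sampling follows
  `sampling = pixel pitch / M` (4.1 µm pitch: 4.1, 2.05, 1.37 µm/px at
  M = 1×, 2×, 3×); defocus blur grows linearly with distance from the focal
  plane at `focus_distance − C`.
* **Sharpness-driven stack acquisition**: a Canny-style edge score (Sobel
  gradient, non-maximum suppression, hysteresis linking at normalized
  thresholds 0.0005/0.002) expressed as edge pixels per frame pixel; a focus
  criterion calibrated from pilot frames as a safety margin over the
  background score; and a stepping loop that runs through the focal region
  and stops after 10 consecutive below-criterion frames (the counter resets
  on any in-focus frame).
* **EDOF fusion and shape-from-focus**: per-pixel variance-of-Laplacian focus
  evidence, argmax frame selection with deterministic tie-breaks, a majority
  filter on the depth-index map, and depth maps at one-C-step resolution.
* **Scale-constrained measurement**: isotropic scaling of reconstructed
  models (ASCII PLY / minimal OBJ) from one two-landmark constraint
  `s = known distance / landmark separation`, 1D distance measurement, and
  validation statistics — signed absolute error `model − reference`, relative
  error `|model − reference| / reference × 100 %`, MAPE, MAE and RMSE in mm
  and µm.
* **Reproducible sessions**: a simulated motion controller that refuses
  out-of-limit moves, resumable per-viewpoint acquisition with a
  deterministic JSON manifest, and summary reports.

## Worked example

Plan a 488-viewpoint sequence, run a small simulated session, and validate
measurements:

```r
library(orbitstack)

base <- plan_orbit(orbit_spec(aiming_point = c(400, 400, 400), radius_mm = 150,
                              azimuth_count = 61, elevation_angles_deg = c(10, 35)))
seq488 <- replicate_with_z_offsets(base, c(-20, 20, 40), limits = axis_limits())
nrow(seq488)
#> [1] 488

object_space_sampling(4.1, 2)   # um per pixel at 2x magnification
#> [1] 2.05

# --- simulated acquisition over 4 viewpoints -------------------------------
aim <- c(400, 400, 400)
sp  <- place_specimen(generate_specimen(seed = 5, size_mm = 8, depth_mm = 4), aim)
cam <- camera_model(sensor_px = c(96, 64), pixel_binning = 30)
sq  <- plan_orbit(orbit_spec(aiming_point = aim, radius_mm = 150,
                             azimuth_count = 4, elevation_angles_deg = 15))
factory <- function(pose, vid)
  twin_frame_source(sp, machine_to_camera(pose), cam, vid)

src1 <- factory(sq[1, , drop = FALSE], 0L)
crit <- calibrate_criterion(  # background = far-defocused pilots
  pilot_background_scores = sapply(c(92, 93, 111, 112),
                                   function(cc) edge_sharpness(src1(cc))),
  pilot_infocus_scores = sapply(c(101, 102, 103, 104),
                                function(cc) edge_sharpness(src1(cc))),
  margin = 1.5)
crit
#> focus criterion: score >= 0.0942383
#>   calibrated from 4 background / 4 in-focus pilot frames (margin 1.5)

man <- run_session(sq, factory, "demo-session",
                   acquisition_config(c_start_mm = 96, c_step_mm = 0.5), crit,
                   session_id = "demo")
summarize_session(man)
#> Session 'demo': 4 viewpoints (4 stacked, 0 acquired, 0 failed, 0 pending)
#>   raw frames: 134 total; per stack mean 33.5 (min 32, max 36)
```

Each stack sweeps the C axis through the specimen and keeps a 10-frame
below-criterion tail; the session directory now holds the raw frames, one
fused EDOF image per viewpoint (`edof/000.tif`, ...) and per-pixel depth
maps.

```r
# --- measurement validation ------------------------------------------------
es <- error_stats(rbind(
  measurement_record("body length",  15.482, 15.474),
  measurement_record("leg segment",   6.128,  6.131),
  measurement_record("inter-ocular",  2.509,  2.507)))
es
#> Measurement validation over 3 distance(s):
#>   body length      model   15.482 mm  ref   15.474 mm  error  +0.008 mm (0.052%)
#>   leg segment      model    6.128 mm  ref    6.131 mm  error  -0.003 mm (0.049%)
#>   inter-ocular     model    2.509 mm  ref    2.507 mm  error  +0.002 mm (0.080%)
#>   MAPE 0.060%   MAE 4.3 um   RMSE 5.1 um
```

Here `model` is a distance picked on the scaled 3D model and `ref` the
corresponding calibrated microscope measurement; MAPE/MAE/RMSE summarize
dimensional accuracy across the measured distances.

A thin command-line wrapper over the same functions ships at
`inst/cli/orbitstack.R` with `plan`, `simulate-acquire`, `stack`, `scale`,
`measure` and `report` subcommands.

## Scope

Physical motor control, camera tethering, and photogrammetric reconstruction
itself are out of scope: the package stops at EDOF image sets and consumes
reconstructed models produced by external tools. See
`vignettes/orbitstack-methods.Rmd` for the full account of models,
parameters and limitations.
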