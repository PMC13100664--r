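# Shared fixtures for the digital-twin tests. Everything is generated in code;
# small frame sizes keep the suite fast while preserving the geometry.

twin_camera <- function(sensor_px = c(128, 96), pixel_binning = 22,
                        blur_gain = 3, focus = 250) {
  camera_model(sensor_px = sensor_px, pixel_binning = pixel_binning,
               blur_gain_px_per_mm = blur_gain, focus_distance_mm = focus)
}

# Camera at `radius` from `aim`, at given azimuth/elevation, aimed at `aim`.
aimed_camera <- function(aim = c(400, 400, 400), radius = 150,
                         a_deg = 0, b_deg = 0) {
  d <- orbitstack:::view_direction_ab(a_deg, b_deg)
  camera_pose(aim - radius * d, d)
}

# Dense textured plate perpendicular to the +X optical axis (for a camera at
# azimuth 0): points in the Y-Z plane at world x = aim_x + depth_offset.
# `v_range` limits vertical extent so two plates can sit in disjoint image
# halves.
plate_points <- function(aim, depth_offset_mm, half_width_mm = 5,
                         v_range_mm = c(-4, 4), pitch_mm = 0.08) {
  ys <- seq(-half_width_mm, half_width_mm, by = pitch_mm)
  zs <- seq(v_range_mm[1], v_range_mm[2], by = pitch_mm)
  g <- expand.grid(y = ys, z = zs)
  cbind(aim[1] + depth_offset_mm, aim[2] + g$y, aim[3] + g$z)
}

# Two textured plates 'sep_mm' apart in depth, occupying the top and bottom
# halves of the frame; returns the specimen plus per-plate world z ranges.
two_plate_specimen <- function(aim = c(400, 400, 400), sep_mm = 4,
                               seed = 7, pitch_mm = 0.08) {
  p_near <- plate_points(aim, -sep_mm / 2, v_range_mm = c(0.5, 4),
                         pitch_mm = pitch_mm)
  p_far <- plate_points(aim, +sep_mm / 2, v_range_mm = c(-4, -0.5),
                        pitch_mm = pitch_mm)
  pts <- rbind(p_near, p_far)
  set.seed(seed)
  synthetic_specimen(pts, intensity = runif(nrow(pts), 0.25, 1),
                     background = 0.08)
  # near plate appears in the top image half (positive v), far in the bottom
}

# High-contrast checkerboard frame: reliably sharp under the edge score.
checker_frame <- function(h = 64, w = 64, cell = 4) {
  ri <- (seq_len(h) - 1) %/% cell
  ci <- (seq_len(w) - 1) %/% cell
  matrix(as.numeric(outer(ri, ci, "+") %% 2), h, w)
}

# Frame source driven by a scripted in-focus pattern: frame index k (0-based,
# from the acquisition's own C positions) is sharp iff pattern[k + 1] is TRUE;
# sharp frames are checkerboards, dull frames uniform background.
scripted_source <- function(pattern, cfg, h = 64, w = 64) {
  sharp <- checker_frame(h, w)
  dull <- matrix(0.2, h, w)
  function(c_pos_mm) {
    k <- round((c_pos_mm - cfg$c_start_mm) / cfg$c_step_mm)
    if (k + 1 <= length(pattern) && isTRUE(pattern[k + 1])) sharp else dull
  }
}

# A criterion that any checkerboard passes and any uniform frame fails.
mid_criterion <- function() focus_criterion(0.05)

# Calibrate a twin criterion from a coarse stacking-axis sweep: the best
# sweep scores serve as in-focus pilots, far-defocused frames as background.
calibrate_from_sweep <- function(source, c_infocus, c_background, margin = 1.5) {
  fo <- vapply(c_infocus, function(cc) edge_sharpness(source(cc)), 0)
  bg <- vapply(c_background, function(cc) edge_sharpness(source(cc)), 0)
  calibrate_criterion(bg, sort(fo, decreasing = TRUE)[seq_len(min(4, length(fo)))],
                      margin = margin)
}
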