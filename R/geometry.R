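#' Axis travel limits of the six-axis rig
#'
#' Closed intervals for each machine axis. Defaults reflect a gantry-style
#' build with roughly 800 mm of travel on each translational axis, continuous
#' azimuth rotation, about +/- 45 degrees of tilt, and 100 mm of usable travel
#' on the focus-stacking axis.
#'
#' @param x,y,z length-2 numeric, translational ranges in mm.
#' @param a length-2 numeric, azimuth range in degrees. A span of 360 degrees
#'   or more means the axis is unbounded and values are compared modulo 360.
#' @param b length-2 numeric, elevation (tilt) range in degrees.
#' @param c length-2 numeric, stacking-axis range in mm.
#' @return An object of class `axis_limits`.
#' @examples
#' axis_limits()
#' axis_limits(b = c(-30, 30))
#' @export
axis_limits <- function(x = base::c(0, 800), y = base::c(0, 800),
                        z = base::c(0, 800), a = base::c(0, 360),
                        b = base::c(-45, 45), c = base::c(0, 100)) {
  lim <- list(x = x, y = y, z = z, a = a, b = b, c = c)
  for (ax in names(lim)) {
    v <- lim[[ax]]
    if (!is.numeric(v) || length(v) != 2L || anyNA(v))
      stop("limit for axis ", toupper(ax), " must be a length-2 numeric")
    if (v[1] > v[2])
      stop("limit for axis ", toupper(ax), " has min > max")
  }
  structure(lim, class = "axis_limits")
}

#' @export
print.axis_limits <- function(x, ...) {
  cat("Axis limits:\n")
  for (ax in names(x))
    cat(sprintf("  %s: [%g, %g] %s\n", toupper(ax), x[[ax]][1], x[[ax]][2],
                if (ax %in% c("a", "b")) "deg" else "mm"))
  invisible(x)
}

#' One machine pose of the rig
#'
#' A single configuration of the six machine axes: three translations (mm),
#' azimuth and elevation of the camera view direction (degrees), and the
#' position of the focus-stacking axis along the optical axis (mm). Azimuth is
#' normalized to `[0, 360)`.
#'
#' @param x,y,z translational coordinates in mm.
#' @param a azimuth in degrees (normalized to `[0, 360)`).
#' @param b elevation/tilt in degrees.
#' @param c stacking-axis position in mm.
#' @return An object of class `machine_pose`.
#' @export
machine_pose <- function(x = 0, y = 0, z = 0, a = 0, b = 0, c = 0) {
  v <- base::c(x = x, y = y, z = z, a = a, b = b, c = c)
  if (!all(is.finite(v))) stop("all machine pose coordinates must be finite")
  p <- list(x = x, y = y, z = z, a = a %% 360, b = b, c = c)
  structure(p, class = "machine_pose")
}

#' @export
print.machine_pose <- function(x, ...) {
  cat(sprintf("machine pose: x=%.3f y=%.3f z=%.3f mm, a=%.3f b=%.3f deg, c=%.3f mm\n",
              x$x, x$y, x$z, x$a, x$b, x$c))
  invisible(x)
}

as_machine_pose <- function(p) {
  if (inherits(p, "machine_pose")) return(p)
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1L)
    return(machine_pose(p$x, p$y, p$z, p$a, p$b, if ("c" %in% names(p)) p$c else 0))
  }
  if (is.numeric(p) && !is.null(names(p)))
    return(do.call(machine_pose, as.list(p)))
  stop("cannot interpret object as a machine pose")
}

#' World-frame camera pose
#'
#' Position of the camera reference point (mm) and the unit view direction
#' pointing from the camera toward the aiming point. The world frame is
#' right-handed with Z vertical.
#'
#' @param position numeric length-3, camera position in mm.
#' @param view_direction numeric length-3; normalized internally, must be
#'   non-zero.
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(position, view_direction) {
  position <- as.numeric(position)
  view_direction <- as.numeric(view_direction)
  if (length(position) != 3L || !all(is.finite(position)))
    stop("position must be a finite length-3 vector")
  if (length(view_direction) != 3L || !all(is.finite(view_direction)))
    stop("view_direction must be a finite length-3 vector")
  n <- sqrt(sum(view_direction^2))
  if (n < 1e-12) stop("view_direction must be non-zero")
  structure(list(position = position, view_direction = view_direction / n),
            class = "camera_pose")
}

#' @export
print.camera_pose <- function(x, ...) {
  cat(sprintf("camera pose: position (%.3f, %.3f, %.3f) mm, view direction (%.4f, %.4f, %.4f)\n",
              x$position[1], x$position[2], x$position[3],
              x$view_direction[1], x$view_direction[2], x$view_direction[3]))
  invisible(x)
}

#' Rig geometry conventions
#'
#' @param c_axis_convention `"toward"` (default) if positive stacking-axis
#'   values move the camera toward the specimen (decreasing working distance),
#'   `"away"` otherwise. Fixed per session.
#' @param home_offset numeric length-3 mm mapping machine origin to world
#'   origin.
#' @return An object of class `rig_geometry`.
#' @export
rig_geometry <- function(c_axis_convention = c("toward", "away"),
                         home_offset = c(0, 0, 0)) {
  c_axis_convention <- match.arg(c_axis_convention)
  home_offset <- as.numeric(home_offset)
  if (length(home_offset) != 3L || !all(is.finite(home_offset)))
    stop("home_offset must be a finite length-3 vector")
  structure(list(c_axis_convention = c_axis_convention,
                 home_offset = home_offset),
            class = "rig_geometry")
}

#' Specification of a camera orbit
#'
#' Describes a set of viewpoints on a sphere about an aiming point: one ring of
#' equally spaced azimuths per elevation angle, optionally replicated at
#' constant vertical offsets to densify coverage.
#'
#' @param aiming_point numeric length-3 mm; the world point the orbit is
#'   centred on and aimed at (the specimen is positioned there).
#' @param radius_mm sphere radius, mm, > 0.
#' @param azimuth_count number of equally spaced azimuths per ring, >= 1.
#' @param elevation_angles_deg numeric vector of ring elevations in degrees.
#' @param z_offsets_mm numeric vector of constant vertical offsets (mm) used by
#'   [replicate_with_z_offsets()]; may be empty.
#' @return An object of class `orbit_spec`.
#' @export
orbit_spec <- function(aiming_point = c(400, 400, 400), radius_mm = 150,
                       azimuth_count = 12, elevation_angles_deg = c(0, 25, 45),
                       z_offsets_mm = numeric()) {
  aiming_point <- as.numeric(aiming_point)
  if (length(aiming_point) != 3L || !all(is.finite(aiming_point)))
    stop("aiming_point must be a finite length-3 vector")
  if (!is.numeric(radius_mm) || radius_mm <= 0) stop("radius_mm must be > 0")
  if (azimuth_count < 1 || azimuth_count != round(azimuth_count))
    stop("azimuth_count must be a positive integer")
  if (length(elevation_angles_deg) < 1)
    stop("at least one elevation angle is required")
  structure(list(aiming_point = aiming_point, radius_mm = radius_mm,
                 azimuth_count = as.integer(azimuth_count),
                 elevation_angles_deg = as.numeric(elevation_angles_deg),
                 z_offsets_mm = as.numeric(z_offsets_mm)),
            class = "orbit_spec")
}

# View direction (unit) from azimuth/elevation in degrees. Azimuth is the
# direction the camera looks, measured counter-clockwise from +X; elevation is
# the angle of the camera above the horizontal plane through the aiming point,
# so a camera looking straight down has b = 90 and view direction (0, 0, -1).
view_direction_ab <- function(a_deg, b_deg) {
  a <- a_deg * pi / 180
  b <- b_deg * pi / 180
  c(cos(b) * cos(a), cos(b) * sin(a), -sin(b))
}

#' Check a machine pose against axis limits
#'
#' @param pose a [machine_pose()] (or a one-row data frame with columns
#'   x, y, z, a, b and optionally c).
#' @param limits an [axis_limits()] object.
#' @return Character vector of human-readable violations; empty when the pose
#'   is within limits. Azimuth is compared modulo 360 when the A axis spans a
#'   full circle.
#' @examples
#' check_limits(machine_pose(400, 400, 400), axis_limits())
#' check_limits(machine_pose(400, 400, 400, b = 46), axis_limits())
#' @export
check_limits <- function(pose, limits = axis_limits()) {
  pose <- as_machine_pose(pose)
  viol <- character()
  for (ax in c("x", "y", "z", "b", "c")) {
    v <- pose[[ax]]
    r <- limits[[ax]]
    if (v < r[1] || v > r[2])
      viol <- c(viol, sprintf("axis %s: %g outside [%g, %g]",
                              toupper(ax), v, r[1], r[2]))
  }
  ra <- limits$a
  if (diff(ra) < 360) {
    av <- pose$a %% 360
    lo <- ra[1] %% 360
    hi <- lo + diff(ra)
    ok <- (av >= lo && av <= hi) || (av + 360 >= lo && av + 360 <= hi)
    if (!ok)
      viol <- c(viol, sprintf("axis A: %g outside [%g, %g]", pose$a, ra[1], ra[2]))
  }
  viol
}

#' Plan a camera-orbit viewpoint sequence
#'
#' Places `azimuth_count` x `length(elevation_angles_deg)` camera positions on
#' a sphere of the requested radius about the aiming point, each aimed at the
#' aiming point, and converts them to machine poses. Poses are ordered ring by
#' ring (elevations in the order given), azimuth ascending from 0. Every
#' returned pose is validated against the axis limits; unreachable poses are an
#' error unless `skip_unreachable = TRUE`, in which case they are dropped with
#' a warning (silent loss of coverage degrades photogrammetric overlap, so the
#' loud default is deliberate).
#'
#' @param spec an [orbit_spec()].
#' @param limits an [axis_limits()].
#' @param rig a [rig_geometry()].
#' @param skip_unreachable drop out-of-limit poses with a warning instead of
#'   failing.
#' @return A data frame of class `orbit_sequence` with columns
#'   `x, y, z, a, b, c` (mm / deg; `c` is always 0 at planning time). Row order
#'   defines the 0-based sequence index.
#' @examples
#' seq4 <- plan_orbit(orbit_spec(azimuth_count = 4, elevation_angles_deg = 0,
#'                               radius_mm = 100))
#' seq4$a
#' @export
plan_orbit <- function(spec, limits = axis_limits(), rig = rig_geometry(),
                       skip_unreachable = FALSE) {
  stopifnot(inherits(spec, "orbit_spec"))
  ws_viol <- check_limits(machine_pose(spec$aiming_point[1] - rig$home_offset[1],
                                       spec$aiming_point[2] - rig$home_offset[2],
                                       spec$aiming_point[3] - rig$home_offset[3]),
                          limits)
  ws_viol <- grep("^axis [XYZ]", ws_viol, value = TRUE)
  if (length(ws_viol))
    stop("aiming point outside translational workspace: ",
         paste(ws_viol, collapse = "; "))

  az <- (seq_len(spec$azimuth_count) - 1) * 360 / spec$azimuth_count
  rows <- list()
  bad <- character()
  for (el in spec$elevation_angles_deg) {
    for (a in az) {
      d <- view_direction_ab(a, el)
      pos <- spec$aiming_point - spec$radius_mm * d
      cam <- camera_pose(pos, d)
      pose <- tryCatch(camera_to_machine(cam, rig, limits),
                       error = function(e) e)
      if (inherits(pose, "error")) {
        bad <- c(bad, sprintf("a=%g b=%g: %s", a, el, conditionMessage(pose)))
        next
      }
      viol <- check_limits(pose, limits)
      if (length(viol)) {
        bad <- c(bad, sprintf("a=%g b=%g: %s", a, el, paste(viol, collapse = "; ")))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(x = pose$x, y = pose$y, z = pose$z,
                                              a = pose$a, b = pose$b, c = 0)
    }
  }
  if (length(bad)) {
    msg <- paste0(length(bad), " unreachable pose(s):\n  ",
                  paste(utils::head(bad, 10L), collapse = "\n  "))
    if (!skip_unreachable) stop(msg) else warning("dropped ", msg)
  }
  if (!length(rows)) stop("no reachable poses in the requested orbit")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("orbit_sequence", "data.frame")
  out
}

#' Replicate a base viewpoint path at constant vertical offsets
#'
#' Densifies viewpoint coverage by repeating a base camera path at one or more
#' constant Z shifts: the output is the base path followed by one full copy per
#' offset with `z` shifted by that constant. Sequence indices are implicit row
#' order starting at 0.
#'
#' @param base an `orbit_sequence` data frame (or any data frame with columns
#'   x, y, z, a, b), non-empty.
#' @param offsets_mm numeric vector of vertical offsets in mm; may be empty, in
#'   which case the base is returned unchanged.
#' @param limits optional [axis_limits()]; when supplied, offsets that push any
#'   pose outside the Z range are an error listing the affected row indices.
#' @return An `orbit_sequence` with `nrow(base) * (1 + length(offsets_mm))`
#'   rows.
#' @export
replicate_with_z_offsets <- function(base, offsets_mm, limits = NULL) {
  if (!is.data.frame(base) || nrow(base) == 0L)
    stop("base sequence must be a non-empty data frame")
  if (!all(c("x", "y", "z", "a", "b") %in% names(base)))
    stop("base sequence must have columns x, y, z, a, b")
  if (!"c" %in% names(base)) base$c <- 0
  out <- base
  for (off in offsets_mm) {
    rep <- base
    rep$z <- rep$z + off
    if (!is.null(limits)) {
      outside <- which(rep$z < limits$z[1] | rep$z > limits$z[2])
      if (length(outside))
        stop(sprintf("z offset %g mm pushes %d pose(s) outside Z range [%g, %g]; base row indices: %s",
                     off, length(outside), limits$z[1], limits$z[2],
                     paste(utils::head(outside - 1L, 20L), collapse = ", ")))
    }
    out <- rbind(out, rep)
  }
  rownames(out) <- NULL
  class(out) <- c("orbit_sequence", "data.frame")
  out
}

#' Convert a world-frame camera pose to a machine pose
#'
#' Inverse kinematics for the gantry + pan/tilt architecture: azimuth is the
#' heading of the view direction (counter-clockwise from +X), elevation is the
#' camera's angle above the horizontal plane through the target, translations
#' are the camera position minus the rig's home offset, and the stacking axis
#' is left at 0.
#'
#' @param cam a [camera_pose()].
#' @param rig a [rig_geometry()].
#' @param limits an [axis_limits()]; a required tilt outside the B range is an
#'   unreachable-pose error.
#' @return A [machine_pose()].
#' @export
camera_to_machine <- function(cam, rig = rig_geometry(), limits = axis_limits()) {
  stopifnot(inherits(cam, "camera_pose"))
  d <- cam$view_direction
  h <- sqrt(d[1]^2 + d[2]^2)
  b <- atan2(-d[3], h) * 180 / pi
  if (b < limits$b[1] - 1e-9 || b > limits$b[2] + 1e-9)
    stop(sprintf("unreachable pose: required tilt b=%.3f deg outside [%g, %g]",
                 b, limits$b[1], limits$b[2]))
  if (h < 1e-12)
    stop("unreachable pose: view direction parallel to the vertical axis")
  a <- (atan2(d[2], d[1]) * 180 / pi) %% 360
  xyz <- cam$position - rig$home_offset
  machine_pose(xyz[1], xyz[2], xyz[3], a, b, 0)
}

#' Convert a machine pose to a world-frame camera pose
#'
#' Forward kinematics: the camera sits at the translational coordinates plus
#' the home offset, displaced along the optical axis by the stacking-axis
#' position (toward the specimen under the `"toward"` convention), looking in
#' the direction given by the azimuth/elevation axes.
#'
#' @param pose a [machine_pose()].
#' @param rig a [rig_geometry()].
#' @return A [camera_pose()].
#' @export
machine_to_camera <- function(pose, rig = rig_geometry()) {
  pose <- as_machine_pose(pose)
  d <- view_direction_ab(pose$a, pose$b)
  sgn <- if (rig$c_axis_convention == "toward") 1 else -1
  pos <- c(pose$x, pose$y, pose$z) + rig$home_offset + sgn * pose$c * d
  camera_pose(pos, d)
}

#' Write / read a viewpoint sequence CSV
#'
#' The on-disk sequence format is a header row `x,y,z,a,b` followed by one
#' comma-separated row per pose, `.` decimal mark, six decimals. Sequence
#' indices are implicit row order starting at 0 (the stacking axis is driven at
#' acquisition time and is not part of the file).
#'
#' @param poses non-empty `orbit_sequence` (or data frame with columns
#'   x, y, z, a, b).
#' @param path file path.
#' @return `write_sequence()` returns `path` invisibly; `read_sequence()`
#'   returns an `orbit_sequence` data frame with `c = 0`.
#' @export
write_sequence <- function(poses, path) {
  if (!is.data.frame(poses) || nrow(poses) == 0L)
    stop("poses must be a non-empty data frame")
  need <- c("x", "y", "z", "a", "b")
  if (!all(need %in% names(poses)))
    stop("poses must have columns x, y, z, a, b")
  body <- apply(as.matrix(poses[need]), 1L,
                function(r) paste(sprintf("%.6f", r), collapse = ","))
  writeLines(c("x,y,z,a,b", body), path)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) stop("sequence file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("schema error: empty sequence file ", path)
  header <- trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  need <- c("x", "y", "z", "a", "b")
  if (!identical(tolower(header), need))
    stop("schema error: expected header 'x,y,z,a,b', got '", lines[1], "'")
  if (length(lines) == 1L)
    stop("schema error: sequence file has no pose rows")
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != 5L)
      stop(sprintf("parse error at line %d: expected 5 fields, found %d",
                   i, length(parts)))
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals))
      stop(sprintf("parse error at line %d: non-numeric field in '%s'",
                   i, lines[i]))
    vals
  })
  m <- do.call(rbind, rows)
  out <- data.frame(x = m[, 1], y = m[, 2], z = m[, 3], a = m[, 4], b = m[, 5],
                    c = 0)
  class(out) <- c("orbit_sequence", "data.frame")
  out
}

#' @export
print.orbit_sequence <- function(x, ...) {
  if (!is.null(x$b))
    cat(sprintf("orbit sequence: %d viewpoints (indices 0-%d), %d distinct elevation(s)\n",
                nrow(x), nrow(x) - 1L, length(unique(round(x$b, 6)))))
  NextMethod()
}

#' Read an orbit configuration file
#'
#' Reads a YAML (or JSON) configuration holding an `orbit` block (aiming point,
#' radius, azimuth count, elevations, z offsets), an optional `limits` block
#' and an optional `rig` block, and returns the corresponding objects.
#'
#' @param path configuration file path.
#' @return List with elements `spec` ([orbit_spec()]), `limits`
#'   ([axis_limits()]) and `rig` ([rig_geometry()]).
#' @export
read_orbit_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  o <- cfg$orbit
  if (is.null(o)) stop("configuration has no 'orbit' block")
  spec <- orbit_spec(
    aiming_point = o$aiming_point,
    radius_mm = o$radius_mm,
    azimuth_count = o$azimuth_count,
    elevation_angles_deg = unlist(o$elevation_angles_deg),
    z_offsets_mm = if (is.null(o$z_offsets_mm)) numeric() else unlist(o$z_offsets_mm))
  lim <- if (is.null(cfg$limits)) axis_limits() else
    do.call(axis_limits, lapply(cfg$limits, unlist))
  rig <- if (is.null(cfg$rig)) rig_geometry() else
    rig_geometry(c_axis_convention = cfg$rig$c_axis_convention %||% "toward",
                 home_offset = unlist(cfg$rig$home_offset %||% c(0, 0, 0)))
  list(spec = spec, limits = lim, rig = rig)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
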