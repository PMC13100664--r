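#' Simulated motion controller
#'
#' Minimal stand-in for the rig's motion firmware: it tracks the current
#' machine pose and refuses any commanded move that violates the axis limits.
#' The position query always reflects the last accepted move.
#'
#' @param limits an [axis_limits()].
#' @param start_pose initial [machine_pose()].
#' @return An object of class `motion_controller`.
#' @export
motion_controller <- function(limits = axis_limits(),
                              start_pose = machine_pose(400, 400, 400)) {
  env <- new.env(parent = emptyenv())
  env$pose <- start_pose
  env$limits <- limits
  structure(list(env = env), class = "motion_controller")
}

#' Command a move; query the current pose
#'
#' `move_to()` returns `TRUE` if the move was accepted; on refusal it returns
#' `FALSE` with the limit violations attached as attribute `"violations"` and
#' leaves the position unchanged. `controller_pose()` returns the last
#' accepted pose.
#'
#' @param ctrl a [motion_controller()].
#' @param pose target [machine_pose()].
#' @return See description.
#' @export
move_to <- function(ctrl, pose) {
  stopifnot(inherits(ctrl, "motion_controller"))
  pose <- as_machine_pose(pose)
  viol <- check_limits(pose, ctrl$env$limits)
  if (length(viol)) {
    out <- FALSE
    attr(out, "violations") <- viol
    return(out)
  }
  ctrl$env$pose <- pose
  TRUE
}

#' @rdname move_to
#' @export
controller_pose <- function(ctrl) {
  stopifnot(inherits(ctrl, "motion_controller"))
  ctrl$env$pose
}

session_log <- function(session_dir, msg) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
      file = file.path(session_dir, "log.txt"), append = TRUE)
}

read_manifest <- function(session_dir) {
  p <- file.path(session_dir, "manifest.json")
  if (!file.exists(p)) return(NULL)
  m <- jsonlite::read_json(p, simplifyVector = FALSE)
  class(m) <- "session_manifest"
  m
}

write_manifest <- function(manifest, session_dir) {
  m <- unclass(manifest)
  jsonlite::write_json(m, file.path(session_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Run an acquisition session over a viewpoint sequence
#'
#' Visits every viewpoint in file order: commands the simulated motion
#' controller to the pose, acquires a focus stack from the frame source,
#' writes the frames and a per-stack manifest into
#' `session_dir/<viewpoint>/`, and (optionally) fuses the stack immediately,
#' writing the extended depth-of-field outputs under `session_dir/edof/`.
#' Sessions are resumable: viewpoints already marked `stacked` (or `acquired`
#' when `fuse = FALSE`) in the manifest are skipped, so interrupting and
#' rerunning never re-acquires completed viewpoints. A controller refusal
#' marks the viewpoint `failed` with the violation text and the session
#' continues. The manifest is deterministic given the inputs; wall-clock
#' timestamps go to the append-only `log.txt`.
#'
#' @param sequence an `orbit_sequence` data frame (see [plan_orbit()],
#'   [read_sequence()]).
#' @param frame_source_factory function `(pose, viewpoint_index) -> frame
#'   source` (see [twin_frame_source()]); `pose` is a [machine_pose()].
#' @param session_dir writable session directory (created if missing).
#' @param cfg an [acquisition_config()].
#' @param criterion a [focus_criterion()].
#' @param rig a [rig_geometry()].
#' @param limits an [axis_limits()].
#' @param fuse fuse each stack into an EDOF image as it is acquired.
#' @param window_px fusion window, see [fuse_stack()].
#' @param write_frames write per-frame PNGs (disable to save disk in large
#'   simulations; stack manifests are always written).
#' @param session_id identifier recorded in the manifest.
#' @return The `session_manifest` (invisibly): session id, config snapshot,
#'   and per-viewpoint status (`pending`/`acquired`/`stacked`/`failed`),
#'   frame counts and failure reasons.
#' @export
run_session <- function(sequence, frame_source_factory, session_dir,
                        cfg = acquisition_config(), criterion,
                        rig = rig_geometry(), limits = axis_limits(),
                        fuse = TRUE, window_px = 9L, write_frames = TRUE,
                        session_id = "session") {
  stopifnot(is.data.frame(sequence), nrow(sequence) >= 1L,
            is.function(frame_source_factory))
  dir.create(session_dir, recursive = TRUE, showWarnings = FALSE)
  if (fuse) dir.create(file.path(session_dir, "edof"), showWarnings = FALSE)
  write_sequence(sequence, file.path(session_dir, "sequence.csv"))
  yaml::write_yaml(unclass(cfg), file.path(session_dir, "config.yaml"))

  manifest <- read_manifest(session_dir)
  if (is.null(manifest)) {
    manifest <- structure(list(
      session_id = session_id,
      config = unclass(cfg),
      criterion_threshold = criterion$threshold,
      sequence = "sequence.csv",
      n_viewpoints = nrow(sequence),
      viewpoints = lapply(seq_len(nrow(sequence)) - 1L, function(i)
        list(index = i, status = "pending", frames = 0L, reason = NULL))),
      class = "session_manifest")
  }
  if (length(manifest$viewpoints) < nrow(sequence)) {
    for (i in seq.int(length(manifest$viewpoints) + 1L, nrow(sequence)))
      manifest$viewpoints[[i]] <- list(index = i - 1L, status = "pending",
                                       frames = 0L, reason = NULL)
    manifest$n_viewpoints <- nrow(sequence)
  }
  ctrl <- motion_controller(limits)
  done_states <- if (fuse) "stacked" else c("acquired", "stacked")

  for (row in seq_len(nrow(sequence))) {
    vid <- row - 1L
    vp <- manifest$viewpoints[[row]]
    if (vp$status %in% done_states) {
      session_log(session_dir, sprintf("viewpoint %d already %s; skipping",
                                       vid, vp$status))
      next
    }
    pose <- as_machine_pose(sequence[row, , drop = FALSE])
    ok <- move_to(ctrl, pose)
    if (!isTRUE(ok)) {
      reason <- paste(attr(ok, "violations"), collapse = "; ")
      session_log(session_dir, sprintf("viewpoint %d REFUSED: %s", vid, reason))
      manifest$viewpoints[[row]] <- list(index = vid, status = "failed",
                                         frames = 0L, reason = reason)
      write_manifest(manifest, session_dir)
      next
    }
    session_log(session_dir,
                sprintf("viewpoint %d: moved to x=%.3f y=%.3f z=%.3f a=%.3f b=%.3f",
                        vid, pose$x, pose$y, pose$z, pose$a, pose$b))
    source <- frame_source_factory(pose, vid)
    stack <- acquire_stack(source, cfg, criterion)
    vdir <- file.path(session_dir, sprintf("%03d", vid))
    dir.create(vdir, showWarnings = FALSE)
    files <- sprintf("frame_%03d.png", seq_along(stack$frames) - 1L)
    if (write_frames)
      for (k in seq_along(stack$frames))
        png::writePNG(pmin(pmax(stack$frames[[k]]$pixels, 0), 1),
                      file.path(vdir, files[k]))
    jsonlite::write_json(list(files = files,
                              c_positions_mm = stack$c_positions_mm,
                              scores = stack$scores,
                              in_focus = stack$in_focus,
                              truncated = stack$truncated),
                         file.path(vdir, "stack.json"),
                         auto_unbox = TRUE, digits = NA)
    for (k in seq_along(stack$frames))
      session_log(session_dir,
                  sprintf("viewpoint %d frame %d: C=%.3f score=%.6f %s",
                          vid, k - 1L, stack$c_positions_mm[k],
                          stack$scores[k],
                          if (stack$in_focus[k]) "in-focus" else "below"))
    status <- "acquired"
    if (fuse) {
      res <- fuse_stack(stack, window_px)
      write_edof(res, file.path(session_dir, "edof", sprintf("%03d", vid)))
      status <- "stacked"
    }
    manifest$viewpoints[[row]] <- list(index = vid, status = status,
                                       frames = length(stack$frames),
                                       reason = NULL)
    write_manifest(manifest, session_dir)
  }
  invisible(manifest)
}

#' Fuse the pending stacks of an existing session
#'
#' Deferred counterpart of `run_session(fuse = TRUE)`: scans the session
#' manifest for viewpoints in state `acquired`, fuses their stacks from the
#' frames on disk and advances them to `stacked`.
#'
#' @param session_dir session directory.
#' @param window_px fusion window.
#' @return The updated `session_manifest`, invisibly.
#' @export
stack_session <- function(session_dir, window_px = 9L) {
  manifest <- read_manifest(session_dir)
  if (is.null(manifest)) stop("no manifest in ", session_dir)
  dir.create(file.path(session_dir, "edof"), showWarnings = FALSE)
  for (row in seq_along(manifest$viewpoints)) {
    vp <- manifest$viewpoints[[row]]
    if (!identical(vp$status, "acquired")) next
    vdir <- file.path(session_dir, sprintf("%03d", vp$index))
    man <- jsonlite::read_json(file.path(vdir, "stack.json"),
                               simplifyVector = TRUE)
    frames <- lapply(seq_along(man$files), function(k)
      new_frame(png::readPNG(file.path(vdir, man$files[k])),
                c_pos_mm = man$c_positions_mm[k]))
    res <- fuse_stack(frames, window_px)
    res$c_positions_mm <- man$c_positions_mm
    write_edof(res, file.path(session_dir, "edof", sprintf("%03d", vp$index)))
    manifest$viewpoints[[row]]$status <- "stacked"
    write_manifest(manifest, session_dir)
  }
  invisible(manifest)
}

#' Summarize a session
#'
#' Per-session totals in the shape of an acquisition report: viewpoints
#' visited, raw frames captured, frames-per-stack statistics and failed
#' viewpoints with reasons.
#'
#' @param manifest a `session_manifest` (as returned by [run_session()]) or a
#'   session directory containing `manifest.json`.
#' @return An object of class `session_summary`.
#' @export
summarize_session <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(manifest)) stop("no session manifest found")
  vps <- manifest$viewpoints
  status <- vapply(vps, function(v) v$status, "")
  frames <- vapply(vps, function(v) as.integer(v$frames), 0L)
  acq <- frames[status %in% c("acquired", "stacked")]
  failures <- lapply(vps[status == "failed"], function(v)
    list(index = v$index, reason = v$reason))
  structure(list(
    session_id = manifest$session_id,
    n_viewpoints = length(vps),
    n_stacked = sum(status == "stacked"),
    n_acquired = sum(status == "acquired"),
    n_failed = sum(status == "failed"),
    n_pending = sum(status == "pending"),
    total_frames = sum(frames),
    frames_per_stack = if (length(acq))
      list(mean = mean(acq), min = min(acq), max = max(acq))
    else list(mean = NA_real_, min = NA_integer_, max = NA_integer_),
    failures = failures), class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("Session '%s': %d viewpoints (%d stacked, %d acquired, %d failed, %d pending)\n",
              x$session_id, x$n_viewpoints, x$n_stacked, x$n_acquired,
              x$n_failed, x$n_pending))
  cat(sprintf("  raw frames: %d total", x$total_frames))
  if (!is.na(x$frames_per_stack$mean))
    cat(sprintf("; per stack mean %.1f (min %d, max %d)",
                x$frames_per_stack$mean, x$frames_per_stack$min,
                x$frames_per_stack$max))
  cat("\n")
  for (f in x$failures)
    cat(sprintf("  FAILED viewpoint %d: %s\n", f$index, f$reason))
  invisible(x)
}
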