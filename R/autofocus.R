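#' Stack-acquisition configuration
#'
#' Parameters of the sharpness-driven focus-stack loop. The hysteresis
#' thresholds are applied to the normalized gradient magnitude of the frame
#' (intensity range `[0, 1]`); defaults of 0.0005 (low) and 0.002 (high) pick
#' up faint specimen edges while rejecting flat background. Acquisition steps
#' the stacking axis and terminates once `stop_after` consecutive frames have
#' scored below the focus criterion, which leaves a conservative margin of
#' out-of-focus frames beyond the focal region.
#'
#' @param low_threshold,high_threshold hysteresis thresholds on normalized
#'   gradient magnitude, `0 < low < high <= 1`.
#' @param stop_after consecutive below-criterion frames that end acquisition
#'   (default 10).
#' @param c_step_mm stacking-axis step between frames, mm (> 0).
#' @param c_start_mm stacking-axis start position, mm.
#' @param max_frames hard safety cap on frames per stack.
#' @param presmooth_sigma Gaussian pre-smoothing (px) applied before the
#'   gradient; 0 disables. Conventional preprocessing for hysteresis edge
#'   detection.
#' @param settle_delay_s informational settling delay of the physical rig;
#'   unused in simulation.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(low_threshold = 0.0005, high_threshold = 0.002,
                               stop_after = 10L, c_step_mm = 0.5,
                               c_start_mm = 0, max_frames = 500L,
                               presmooth_sigma = 1, settle_delay_s = 0) {
  if (!(low_threshold > 0 && low_threshold < high_threshold && high_threshold <= 1))
    stop("thresholds must satisfy 0 < low < high <= 1")
  if (stop_after < 1) stop("stop_after must be >= 1")
  if (c_step_mm <= 0) stop("c_step_mm must be > 0")
  if (max_frames < 1) stop("max_frames must be >= 1")
  structure(list(low_threshold = low_threshold, high_threshold = high_threshold,
                 stop_after = as.integer(stop_after), c_step_mm = c_step_mm,
                 c_start_mm = c_start_mm, max_frames = as.integer(max_frames),
                 presmooth_sigma = presmooth_sigma,
                 settle_delay_s = settle_delay_s),
            class = "acquisition_config")
}

#' Focus criterion
#'
#' Minimum edge-sharpness score at which a frame counts as in focus, together
#' with a record of how it was derived (see [calibrate_criterion()]).
#'
#' @param threshold positive sharpness score.
#' @param provenance optional list describing the pilot stacks and margin.
#' @return An object of class `focus_criterion`.
#' @export
focus_criterion <- function(threshold, provenance = NULL) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  structure(list(threshold = threshold, provenance = provenance),
            class = "focus_criterion")
}

#' @export
print.focus_criterion <- function(x, ...) {
  cat(sprintf("focus criterion: score >= %g\n", x$threshold))
  if (!is.null(x$provenance))
    cat(sprintf("  calibrated from %d background / %d in-focus pilot frames (margin %g)\n",
                x$provenance$n_background, x$provenance$n_infocus,
                x$provenance$margin))
  invisible(x)
}

#' Edge-based sharpness score
#'
#' Fraction of pixels that belong to an edge, detected Canny-style: Sobel
#' gradient (scaled so a full-contrast step edge has magnitude 0.5), then
#' non-maximum suppression along the quantized gradient direction (ties kept,
#' so gradient plateaus such as an ideal step edge survive intact), then
#' hysteresis linking — pixels at or above the high threshold seed edges,
#' which extend through 8-connected suppressed-gradient pixels at or above
#' the low threshold. The thinning step is what makes the score peak in
#' focus: a defocused boundary collapses to a single faint ridge while an
#' in-focus textured surface contributes many ridges. Normalizing by the
#' pixel count makes the score resolution-independent, and the gradient makes
#' it invariant to adding a constant to all intensities. RGB frames are
#' scored on luminance.
#'
#' @param frame an [new_frame()] object or numeric matrix in `[0, 1]`.
#' @param low,high hysteresis thresholds (normalized units).
#' @param presmooth_sigma Gaussian pre-smoothing sigma in px; 0 disables.
#' @return Score in `[0, 1]`: edge pixels / total pixels.
#' @examples
#' edge_sharpness(matrix(0.5, 32, 32))  # uniform -> 0
#' @export
edge_sharpness <- function(frame, low = 0.0005, high = 0.002,
                           presmooth_sigma = 1) {
  px <- luminance(frame_pixels(frame))
  if (!is.matrix(px) || min(dim(px)) <= 2L)
    stop("frame must be larger than 2 x 2")
  if (!(low > 0 && low < high))
    stop("thresholds must satisfy 0 < low < high")
  if (presmooth_sigma > 0)
    px <- as.matrix(EBImage::gblur(px, sigma = presmooth_sigma))
  # Sobel via shifted matrices: exact arithmetic (no FFT round-off), borders
  # replicated by index clamping
  NW <- shift_mat(px, -1, -1); N <- shift_mat(px, -1, 0); NE <- shift_mat(px, -1, 1)
  W  <- shift_mat(px,  0, -1);                            E  <- shift_mat(px,  0, 1)
  SW <- shift_mat(px,  1, -1); S <- shift_mat(px,  1, 0); SE <- shift_mat(px,  1, 1)
  gx <- ((NE + 2 * E + SE) - (NW + 2 * W + SW)) / 8
  gy <- ((SW + 2 * S + SE) - (NW + 2 * N + NE)) / 8
  g <- sqrt(gx^2 + gy^2)
  ridge <- nonmax_suppress(g, gx, gy)
  strong <- ridge & g >= high
  if (!any(strong)) return(0)
  weak <- ridge & g >= low
  lab <- EBImage::bwlabel(weak)
  keep <- setdiff(unique(lab[strong]), 0)
  sum(lab %in% keep) / length(px)
}

# Shift a matrix by (dr, dc) with replicated borders.
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
  m[ri, ci, drop = FALSE]
}

# Non-maximum suppression of gradient magnitude along the gradient direction
# quantized to 4 sectors; comparisons allow a tiny tolerance so gradient
# plateaus (and their floating-point perturbations after pre-smoothing)
# survive on both sides.
nonmax_suppress <- function(g, gx, gy, tol = 1e-9) {
  ang <- atan2(gy, gx)              # gy along rows (down), gx along columns
  ang <- ang %% pi
  sector <- floor(((ang + pi / 8) %% pi) / (pi / 4))  # 0..3
  keep <- matrix(FALSE, nrow(g), ncol(g))
  nb <- list(`0` = c(0L, 1L),   # gradient ~ horizontal: compare left/right
             `1` = c(1L, 1L),   # 45 deg
             `2` = c(1L, 0L),   # vertical: compare up/down
             `3` = c(1L, -1L))  # 135 deg
  for (s in 0:3) {
    d <- nb[[as.character(s)]]
    sel <- sector == s
    if (!any(sel)) next
    n1 <- shift_mat(g, d[1], d[2])
    n2 <- shift_mat(g, -d[1], -d[2])
    keep[sel] <- g[sel] >= n1[sel] - tol & g[sel] >= n2[sel] - tol
  }
  keep
}

#' Calibrate the focus criterion from pilot stacks
#'
#' Empirical criterion choice: the threshold is a safety margin times the
#' largest sharpness score observed on background-only pilot frames, so that
#' persistent background noise never counts as in focus. Calibration fails if
#' the margin pushes the threshold to or above the weakest in-focus pilot
#' score, i.e. if the two populations are not separable.
#'
#' @param pilot_background_scores sharpness scores of background-only pilot
#'   frames (same optics, illumination and exposure as the scan).
#' @param pilot_infocus_scores sharpness scores of in-focus pilot frames.
#' @param margin multiplicative safety margin (default 2).
#' @return A [focus_criterion()] with provenance.
#' @export
calibrate_criterion <- function(pilot_background_scores, pilot_infocus_scores,
                                margin = 2) {
  if (!length(pilot_background_scores) || !length(pilot_infocus_scores))
    stop("both pilot score lists must be non-empty")
  if (margin <= 0) stop("margin must be > 0")
  bg_max <- max(pilot_background_scores)
  if_min <- min(pilot_infocus_scores)
  threshold <- margin * bg_max
  if (threshold <= 0)
    stop("background pilots all score 0; cannot set a positive criterion (add background noise frames)")
  if (threshold >= if_min)
    stop(sprintf(paste0("pilot populations not separable at margin %g: ",
                        "max background score %g gives threshold %g >= min in-focus score %g"),
                 margin, bg_max, threshold, if_min))
  focus_criterion(threshold,
                  provenance = list(n_background = length(pilot_background_scores),
                                    n_infocus = length(pilot_infocus_scores),
                                    max_background = bg_max,
                                    min_infocus = if_min, margin = margin))
}

#' Acquire a focus stack from a frame source
#'
#' Steps the stacking axis from `c_start_mm` in increments of `c_step_mm`,
#' scoring each frame with [edge_sharpness()]. Acquisition continues through
#' the in-focus region and stops as soon as `stop_after` consecutive frames
#' have scored below the focus criterion (the counter resets on any in-focus
#' frame); if no frame is ever in focus it stops after `stop_after` frames.
#' Below-criterion trailing frames are retained in the stack — they are cheap
#' insurance for the fuser — and flagged so downstream code can down-weight
#' them. A hard `max_frames` cap guarantees termination; hitting it while
#' frames are still in focus records a truncation warning in the stack.
#'
#' @param source a frame source: a function taking a stacking-axis position
#'   (mm) and returning a frame (see [twin_frame_source()] and
#'   [dir_frame_source()]).
#' @param cfg an [acquisition_config()].
#' @param criterion a [focus_criterion()].
#' @return An object of class `focus_stack`: list with `frames` (list of
#'   `of_frame`), `c_positions_mm`, `scores`, `in_focus` (logical flags) and
#'   `truncated`.
#' @export
acquire_stack <- function(source, cfg = acquisition_config(), criterion) {
  stopifnot(is.function(source), inherits(cfg, "acquisition_config"),
            inherits(criterion, "focus_criterion"))
  frames <- list(); cpos <- numeric(); scores <- numeric(); flags <- logical()
  below_run <- 0L
  truncated <- FALSE
  i <- 0L
  repeat {
    cp <- cfg$c_start_mm + i * cfg$c_step_mm
    f <- source(cp)
    if (!inherits(f, "of_frame")) f <- new_frame(f, c_pos_mm = cp)
    s <- edge_sharpness(f, cfg$low_threshold, cfg$high_threshold,
                        cfg$presmooth_sigma)
    f$meta$c_pos_mm <- cp
    f$meta$score <- s
    infocus <- s >= criterion$threshold
    frames[[i + 1L]] <- f
    cpos <- c(cpos, cp); scores <- c(scores, s); flags <- c(flags, infocus)
    below_run <- if (infocus) 0L else below_run + 1L
    i <- i + 1L
    if (below_run >= cfg$stop_after) break
    if (i >= cfg$max_frames) {
      truncated <- any(utils::tail(flags, cfg$stop_after))
      break
    }
  }
  structure(list(frames = frames, c_positions_mm = cpos, scores = scores,
                 in_focus = flags, truncated = truncated, config = cfg,
                 criterion = criterion),
            class = "focus_stack")
}

#' @export
print.focus_stack <- function(x, ...) {
  cat(sprintf("focus stack: %d frames, C %g to %g mm, %d in focus%s\n",
              length(x$frames), min(x$c_positions_mm), max(x$c_positions_mm),
              sum(x$in_focus), if (x$truncated) " [TRUNCATED]" else ""))
  invisible(x)
}

#' @export
length.focus_stack <- function(x) length(x$frames)

#' @export
as.data.frame.focus_stack <- function(x, ...) {
  data.frame(frame = seq_along(x$frames) - 1L, c_pos_mm = x$c_positions_mm,
             score = x$scores, in_focus = x$in_focus)
}

#' Frame sources
#'
#' A frame source is a function mapping a stacking-axis position (mm) to a
#' frame; [acquire_stack()] is agnostic to where frames come from.
#' `twin_frame_source()` renders them with the digital twin;
#' `dir_frame_source()` serves pre-captured frames from a directory containing
#' a `stack.json` manifest (fields `files` and `c_positions_mm`), returning
#' the frame whose recorded position is nearest the requested one.
#'
#' @param specimen a `synthetic_specimen`.
#' @param cam_pose a [camera_pose()].
#' @param model a [camera_model()].
#' @param viewpoint viewpoint index stored in frame metadata.
#' @param dir directory holding PNG frames and `stack.json`.
#' @return A function `(c_pos_mm) -> of_frame`.
#' @export
twin_frame_source <- function(specimen, cam_pose, model, viewpoint = NA_integer_) {
  force(specimen); force(cam_pose); force(model); force(viewpoint)
  function(c_pos_mm) {
    f <- render_frame(specimen, cam_pose, model, c_pos_mm)
    f$meta$viewpoint <- viewpoint
    f
  }
}

#' @rdname twin_frame_source
#' @export
dir_frame_source <- function(dir) {
  manifest_path <- file.path(dir, "stack.json")
  if (!file.exists(manifest_path))
    stop("no stack.json manifest in ", dir)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(man$files) || is.null(man$c_positions_mm) ||
      length(man$files) != length(man$c_positions_mm))
    stop("stack.json must hold parallel 'files' and 'c_positions_mm'")
  files <- file.path(dir, man$files)
  cpos <- as.numeric(man$c_positions_mm)
  function(c_pos_mm) {
    k <- which.min(abs(cpos - c_pos_mm))
    new_frame(png::readPNG(files[k]), c_pos_mm = cpos[k])
  }
}
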