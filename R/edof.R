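#' Per-pixel local sharpness map
#'
#' Local variance of the Laplacian response within a square window — the
#' standard shape-from-focus focus measure. Zero on uniform regions,
#' deterministic, and computed with replicated borders so frame edges do not
#' generate spurious focus evidence.
#'
#' @param frame an [new_frame()] or numeric matrix in `[0, 1]`; RGB frames are
#'   measured on luminance.
#' @param window_px odd window size >= 3 and smaller than the frame.
#' @return Numeric matrix of non-negative local sharpness values, same
#'   dimensions as the frame.
#' @export
local_sharpness_map <- function(frame, window_px = 9L) {
  px <- luminance(frame_pixels(frame))
  if (!is.matrix(px)) stop("frame must be a 2D image")
  if (window_px < 3L || window_px %% 2L == 0L || window_px >= min(dim(px)))
    stop("window_px must be odd, >= 3 and smaller than the frame")
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  L <- as.matrix(EBImage::filter2(px, lap, boundary = "replicate"))
  box <- matrix(1 / window_px^2, window_px, window_px)
  m1 <- as.matrix(EBImage::filter2(L, box, boundary = "replicate"))
  m2 <- as.matrix(EBImage::filter2(L^2, box, boundary = "replicate"))
  pmax(m2 - m1^2, 0)
}

#' Fuse a focus stack into an extended depth-of-field image
#'
#' For every pixel the frame with the highest local sharpness is selected
#' (ties break to the lowest frame index, deterministically), the resulting
#' depth-index map is cleaned with a 3 x 3 majority (mode) filter to suppress
#' salt-and-pepper index noise, and the fused image takes each pixel from its
#' selected frame. Pixels whose best local sharpness falls below
#' `sharpness_floor` carry no focus evidence (untextured background); they
#' take the median frame's value and the sentinel depth index -1. No
#' inter-frame registration is performed: magnification is constant within a
#' stack by construction of the acquisition geometry.
#'
#' @param stack a `focus_stack` (or plain list of frames/matrices of equal
#'   dimensions).
#' @param window_px odd window for [local_sharpness_map()].
#' @param sharpness_floor minimum best-sharpness for a pixel to receive a
#'   depth index.
#' @return An object of class `edof_result`: `image` (fused matrix or RGB
#'   array), `depth_index` (integer matrix, 0-based frame index, -1 =
#'   no evidence) and `c_positions_mm` (stacking-axis position per index).
#' @export
fuse_stack <- function(stack, window_px = 9L, sharpness_floor = 1e-6) {
  frames <- if (inherits(stack, "focus_stack")) stack$frames else stack
  if (!length(frames)) stop("stack must contain at least one frame")
  cpos <- if (inherits(stack, "focus_stack")) stack$c_positions_mm
          else vapply(frames, function(f)
            if (inherits(f, "of_frame")) f$meta$c_pos_mm else NA_real_, 0)
  pix <- lapply(frames, frame_pixels)
  dims <- lapply(pix, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all frames in a stack must have identical dimensions")
  n <- length(pix)
  H <- dims[[1]][1]; W <- dims[[1]][2]

  if (n == 1L) {
    return(structure(list(image = pix[[1]],
                          depth_index = matrix(0L, H, W),
                          c_positions_mm = cpos),
                     class = "edof_result"))
  }

  M <- vapply(pix, function(p) as.vector(local_sharpness_map(p, window_px)),
              numeric(H * W))
  best <- max.col(M, ties.method = "first")
  bestval <- M[cbind(seq_len(H * W), best)]
  idx <- matrix(best - 1L, H, W)
  idx[matrix(bestval < sharpness_floor, H, W)] <- -1L

  idx <- mode_filter3(idx)
  idx[matrix(bestval < sharpness_floor, H, W)] <- -1L

  med <- (n + 1L) %/% 2L
  sel <- idx
  sel[sel < 0L] <- med - 1L
  fused <- compose_from_index(pix, sel)
  structure(list(image = fused, depth_index = idx, c_positions_mm = cpos),
            class = "edof_result")
}

# 3x3 majority filter on an integer label matrix; ties break to the smallest
# label so results are deterministic across platforms.
mode_filter3 <- function(idx) {
  vals <- sort(unique(as.vector(idx)))
  if (length(vals) == 1L) return(idx)
  ones <- matrix(1, 3, 3)
  best_cnt <- matrix(-1, nrow(idx), ncol(idx))
  out <- idx
  for (v in vals) {
    cnt <- round(as.matrix(EBImage::filter2((idx == v) * 1, ones,
                                            boundary = "replicate")))
    sel <- cnt > best_cnt
    out[sel] <- v
    best_cnt[sel] <- cnt[sel]
  }
  out
}

# Assemble an image taking each pixel from the frame named by a 0-based index
# matrix (handles grayscale matrices and RGB arrays).
compose_from_index <- function(pix, sel0) {
  H <- nrow(sel0); W <- ncol(sel0)
  lin <- seq_len(H * W)
  if (length(dim(pix[[1]])) == 3L) {
    out <- array(0, dim(pix[[1]]))
    for (ch in 1:3) {
      plane <- vapply(pix, function(p) as.vector(p[, , ch]), numeric(H * W))
      out[, , ch] <- matrix(plane[cbind(lin, as.vector(sel0) + 1L)], H, W)
    }
    out
  } else {
    plane <- vapply(pix, as.vector, numeric(H * W))
    matrix(plane[cbind(lin, as.vector(sel0) + 1L)], H, W)
  }
}

#' @export
print.edof_result <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("EDOF result: %d x %d image fused from %d frame(s); %.1f%% of pixels carry depth evidence\n",
              d[2], d[1], length(x$c_positions_mm),
              100 * mean(x$depth_index >= 0)))
  invisible(x)
}

#' Coarse depth from a focus stack (shape-from-focus)
#'
#' Maps each pixel's selected depth index to the stacking-axis position of the
#' contributing frame, giving a per-pixel height map in mm (relative to the
#' stacking axis). Pixels without focus evidence are `NA`. Depth resolution is
#' one stacking-axis step.
#'
#' @param stack a `focus_stack` with at least two frames at distinct
#'   stacking-axis positions.
#' @param window_px odd window for [local_sharpness_map()].
#' @param sharpness_floor see [fuse_stack()].
#' @return Numeric matrix of heights in mm (`NA` where untextured).
#' @export
depth_from_stack <- function(stack, window_px = 9L, sharpness_floor = 1e-6) {
  frames <- if (inherits(stack, "focus_stack")) stack$frames else stack
  if (length(frames) < 2L)
    stop("depth recovery needs at least two frames")
  res <- fuse_stack(stack, window_px, sharpness_floor)
  cpos <- res$c_positions_mm
  if (anyNA(cpos) || length(unique(cpos)) < 2L)
    stop("frames must carry at least two distinct stacking-axis positions")
  h <- matrix(NA_real_, nrow(res$depth_index), ncol(res$depth_index))
  ok <- res$depth_index >= 0L
  h[ok] <- cpos[res$depth_index[ok] + 1L]
  h
}

#' Write an EDOF result to disk
#'
#' Writes the fused image as 16-bit TIFF (plus an 8-bit PNG preview), the
#' depth-index map as 16-bit TIFF (stored as index + 1, so the sentinel
#' becomes 0), and the depth map in mm as a 32-bit float TIFF normalized to
#' `[0, 1]` with a JSON sidecar recording the `offset`/`scale` needed to
#' recover millimetres (`mm = offset + scale * stored`) and the stacking-axis
#' positions.
#'
#' @param result an `edof_result`.
#' @param prefix output path prefix; files `<prefix>.tif`, `<prefix>.png`,
#'   `<prefix>_depth_index.tif`, `<prefix>_depth_mm.tif` and
#'   `<prefix>_depth.json` are produced.
#' @return Invisibly, the named vector of file paths.
#' @export
write_edof <- function(result, prefix) {
  stopifnot(inherits(result, "edof_result"))
  img <- pmin(pmax(result$image, 0), 1)
  tif_img_path <- paste0(prefix, ".tif")
  tiff::writeTIFF(img, tif_img_path, bits.per.sample = 16L,
                  compression = "none")
  img_path <- paste0(prefix, ".png")
  png::writePNG(img, img_path)
  idx_path <- paste0(prefix, "_depth_index.tif")
  tiff::writeTIFF((result$depth_index + 1L) / 65535, idx_path,
                  bits.per.sample = 16L, compression = "none")
  cpos <- result$c_positions_mm
  depth <- matrix(NA_real_, nrow(result$depth_index), ncol(result$depth_index))
  ok <- result$depth_index >= 0L
  if (any(ok)) depth[ok] <- cpos[result$depth_index[ok] + 1L]
  rng <- range(depth[ok], 0)
  scale <- max(diff(rng), 1e-12)
  norm <- (depth - rng[1]) / scale
  norm[!ok] <- 0
  tif_path <- paste0(prefix, "_depth_mm.tif")
  tiff::writeTIFF(norm, tif_path, bits.per.sample = 32L, compression = "none")
  meta_path <- paste0(prefix, "_depth.json")
  jsonlite::write_json(list(offset = rng[1], scale = scale,
                            c_positions_mm = cpos,
                            sentinel = "depth-index PNG value 0"),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = tif_img_path, preview = img_path,
              depth_index = idx_path, depth_mm = tif_path, meta = meta_path))
}
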