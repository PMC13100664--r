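#' Digital-twin camera model
#'
#' Fixed-magnification thin-lens camera used by the simulator. Magnification
#' is constant within a scan (the physical analogue keeps bellows extension
#' fixed and steps the whole camera along the optical axis instead of
#' refocusing), so frames in a stack share one scale and the fuser needs no
#' inter-frame registration. Defocus follows a linear model: blur radius in
#' pixels grows as `blur_gain_px_per_mm` times the depth offset from the focal
#' plane.
#'
#' @param pixel_pitch_um physical sensor pixel size, micrometres.
#' @param sensor_px integer length-2, simulated frame width and height in
#'   pixels. The default 512 x 341 keeps the 3:2 aspect of a 5472 x 3648
#'   sensor at about 1/10.7 scale for desk-scale speed.
#' @param magnification optical magnification M (> 0), image size on sensor
#'   over object size.
#' @param focus_distance_mm distance from the camera reference point to the
#'   in-focus object plane when the stacking axis is at 0.
#' @param blur_gain_px_per_mm defocus blur radius (px) per mm of depth offset;
#'   0 disables defocus.
#' @param pixel_binning physical pixels per simulated pixel (matches the
#'   default sensor downscale, so the simulated object-space sampling is
#'   `pixel_pitch_um * pixel_binning / magnification`).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(pixel_pitch_um = 4.1, sensor_px = c(512, 341),
                         magnification = 1, focus_distance_mm = 250,
                         blur_gain_px_per_mm = 3, pixel_binning = 10.7) {
  if (pixel_pitch_um <= 0) stop("pixel_pitch_um must be > 0")
  if (magnification <= 0) stop("magnification must be > 0")
  if (blur_gain_px_per_mm < 0) stop("blur_gain_px_per_mm must be >= 0")
  sensor_px <- as.integer(sensor_px)
  if (length(sensor_px) != 2L || any(sensor_px < 8L))
    stop("sensor_px must be two integers >= 8")
  structure(list(pixel_pitch_um = pixel_pitch_um, sensor_px = sensor_px,
                 magnification = magnification,
                 focus_distance_mm = focus_distance_mm,
                 blur_gain_px_per_mm = blur_gain_px_per_mm,
                 pixel_binning = pixel_binning,
                 mm_per_px = pixel_pitch_um * pixel_binning /
                   (1000 * magnification)),
            class = "camera_model")
}

#' Object-space sampling
#'
#' Physical size one sensor pixel covers on the specimen: pixel pitch divided
#' by magnification. This is an upper bound on recoverable detail, not a
#' guaranteed resolution.
#'
#' @param pixel_pitch_um sensor pixel size in micrometres.
#' @param magnification optical magnification M, must be > 0.
#' @return Micrometres per pixel in object space.
#' @examples
#' object_space_sampling(4.1, 1)  # 4.1 um/px
#' object_space_sampling(4.1, 2)  # 2.05 um/px
#' @export
object_space_sampling <- function(pixel_pitch_um, magnification) {
  if (any(magnification <= 0)) stop("magnification must be > 0")
  if (any(pixel_pitch_um <= 0)) stop("pixel_pitch_um must be > 0")
  pixel_pitch_um / magnification
}

#' Defocus blur radius
#'
#' Linear defocus model: blur radius in pixels is the blur gain times the
#' absolute depth offset from the focal plane; zero at the focal plane and
#' symmetric about it.
#'
#' @param depth_offset_mm signed distance(s) from the focal plane, mm.
#' @param blur_gain_px_per_mm blur radius growth per mm, >= 0.
#' @return Blur radius (px), same length as `depth_offset_mm`.
#' @export
defocus_radius <- function(depth_offset_mm, blur_gain_px_per_mm) {
  if (blur_gain_px_per_mm < 0) stop("blur_gain_px_per_mm must be >= 0")
  blur_gain_px_per_mm * abs(depth_offset_mm)
}

#' A captured (or rendered) frame
#'
#' @param pixels numeric matrix (grayscale) or H x W x 3 array (RGB) with
#'   values in `[0, 1]`.
#' @param viewpoint integer viewpoint index, or `NA`.
#' @param c_pos_mm stacking-axis position the frame was taken at.
#' @param score optional sharpness score.
#' @return An object of class `of_frame`.
#' @export
new_frame <- function(pixels, viewpoint = NA_integer_, c_pos_mm = NA_real_,
                      score = NA_real_) {
  if (!is.numeric(pixels) || !(length(dim(pixels)) %in% c(2L, 3L)))
    stop("pixels must be a numeric matrix or H x W x 3 array")
  structure(list(pixels = pixels,
                 meta = list(viewpoint = viewpoint, c_pos_mm = c_pos_mm,
                             score = score)),
            class = "of_frame")
}

#' @export
print.of_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("frame %d x %d%s, viewpoint %s, C = %s mm, score = %s\n",
              d[2], d[1], if (length(d) == 3L) " RGB" else "",
              format(x$meta$viewpoint), format(x$meta$c_pos_mm),
              format(x$meta$score)))
  invisible(x)
}

# Fast deterministic Gaussian-approximating blur: three iterated box means
# per axis (cumsum-based, O(HW) independent of sigma), replicated borders.
# Used by the renderer where exact Gaussian shape is irrelevant; callers that
# need a true Gaussian use EBImage::gblur.
box_mean_cols <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  # column-wise cumsum without an R-level loop, zero row prepended
  cs <- matrix(cumsum(m), H, W)
  if (W > 1L) cs <- cs - rep(c(0, cs[H, -W]), each = H)
  cs0 <- rbind(0, cs)
  hi <- pmin(seq_len(H) + r, H)
  lo <- pmax(seq_len(H) - r, 1L)
  (cs0[hi + 1L, , drop = FALSE] - cs0[lo, , drop = FALSE]) / (hi - lo + 1L)
}

approx_gauss_blur <- function(m, sigma) {
  if (sigma <= 0.3) return(m)
  r <- max(1L, round(0.5 * (sqrt(2 * sigma^2 + 1) - 1)))
  m <- box_mean_cols(box_mean_cols(m, r), r)
  m <- t(m)
  m <- box_mean_cols(box_mean_cols(m, r), r)
  t(m)
}

frame_pixels <- function(frame) {
  if (inherits(frame, "of_frame")) frame$pixels else frame
}

# Luminance of a frame: identity for grayscale, Rec.709 weights for RGB.
luminance <- function(px) {
  if (length(dim(px)) == 3L)
    0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
  else px
}

#' Generate a synthetic textured specimen
#'
#' Builds a reproducible point-sampled specimen for the digital twin: a
#' dome-shaped textured surface with exactly the requested lateral size and
#' depth extent, a pair of mount landmarks at an exactly known separation (the
#' stand-in for caliper-marked points on a physical specimen mount), and
#' random high-frequency intensity texture so in-focus frames produce dense
#' edges against a uniform background.
#'
#' @param seed integer RNG seed; the same seed always yields the same
#'   specimen. The global RNG state is restored on exit.
#' @param size_mm lateral extent along X, mm (> 0); extent along Y is 0.6 x
#'   this.
#' @param depth_mm exact bounding depth along Z, mm (> 0), centred on 0.
#' @param texture_density surface samples per mm^2 of projected area.
#' @param background uniform background intensity in `[0, 1)`.
#' @return An object of class `synthetic_specimen` with fields `points` (n x 3
#'   mm, local coordinates centred on the origin), `intensity` (length n in
#'   `[0, 1]`), `landmarks` (named list of point pairs with exact distances),
#'   `background` and `origin` (world position of the local origin).
#' @export
generate_specimen <- function(seed = 1L, size_mm = 10, depth_mm = 5,
                              texture_density = 800, background = 0.45) {
  if (size_mm <= 0 || depth_mm <= 0 || texture_density <= 0)
    stop("size_mm, depth_mm and texture_density must be positive")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  ax <- size_mm / 2; ay <- 0.6 * size_mm / 2; az <- depth_mm
  n <- max(200L, round(texture_density * size_mm * (0.6 * size_mm)))
  # upper half-ellipsoid, roughly uniform over direction
  u <- stats::runif(n, -1, 1); phi <- stats::runif(n, 0, 2 * pi)
  w <- sqrt(pmax(0, 1 - u^2))
  dirs <- cbind(w * cos(phi), w * sin(phi), abs(u))
  pts <- cbind(ax * dirs[, 1], ay * dirs[, 2], az * dirs[, 3])
  # rescale each axis so the bounding extents are exact
  for (j in 1:3) {
    r <- range(pts[, j])
    tgt <- c(ax, ay, if (j == 3) depth_mm else NA)[min(j, 3)]
    span <- if (j == 1) size_mm else if (j == 2) 0.6 * size_mm else depth_mm
    if (diff(r) < 1e-9) stop("degenerate specimen sample")
    pts[, j] <- (pts[, j] - r[1]) / diff(r) * span - span / 2
  }
  # blotchy high-frequency texture: a soft-thresholded sum of random plane
  # waves (wavelengths 0.15-1.2 mm), so intensity is spatially coherent at
  # sub-mm scale regardless of how densely the surface is sampled
  K <- 24L
  th <- stats::runif(K, 0, pi); ph2 <- stats::runif(K, 0, 2 * pi)
  dirs <- cbind(sin(th) * cos(ph2), sin(th) * sin(ph2), cos(th))
  freq <- 2 * pi / stats::runif(K, 0.08, 0.5)
  amp <- stats::runif(K, 0.5, 1) / sqrt(K)
  phase <- stats::runif(K, 0, 2 * pi)
  fld <- (pts %*% t(dirs * freq))
  s <- as.vector(cos(sweep(fld, 2L, phase, "+")) %*% amp)
  intensity <- 0.5 + 0.45 * tanh(2.5 * s)

  i_xmin <- which.min(pts[, 1]); i_xmax <- which.max(pts[, 1])
  i_zmin <- which.min(pts[, 3]); i_zmax <- which.max(pts[, 3])
  mount_a <- c(-0.7 * size_mm, 0, -depth_mm / 2)
  mount_b <- c(0.7 * size_mm, 0, -depth_mm / 2)
  mk <- function(p, q) list(a = p, b = q, distance_mm = sqrt(sum((p - q)^2)))
  landmarks <- list(
    mount_bar   = mk(mount_a, mount_b),
    body_length = mk(pts[i_xmin, ], pts[i_xmax, ]),
    body_depth  = mk(pts[i_zmin, ], pts[i_zmax, ]))

  structure(list(points = pts, intensity = intensity, landmarks = landmarks,
                 background = background, origin = c(0, 0, 0),
                 size_mm = size_mm, depth_mm = depth_mm, seed = seed),
            class = "synthetic_specimen")
}

#' Construct a specimen from explicit surface samples
#'
#' Lower-level companion to [generate_specimen()] for building exactly
#' controlled scenes (flat plates, two-plane targets) in tests and
#' demonstrations.
#'
#' @param points n x 3 numeric matrix of surface samples, mm.
#' @param intensity length-n intensities in `[0, 1]` (recycled).
#' @param landmarks named list of `list(a =, b =, distance_mm =)` entries.
#' @param background uniform background intensity.
#' @param origin world position of the local origin, mm.
#' @return A `synthetic_specimen`.
#' @export
synthetic_specimen <- function(points, intensity = 0.8, landmarks = list(),
                               background = 0.08, origin = c(0, 0, 0)) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 1L)
    stop("points must be a non-empty n x 3 matrix")
  intensity <- rep_len(intensity, nrow(points))
  structure(list(points = points, intensity = intensity, landmarks = landmarks,
                 background = background, origin = as.numeric(origin)),
            class = "synthetic_specimen")
}

#' @export
print.synthetic_specimen <- function(x, ...) {
  cat(sprintf("synthetic specimen: %d surface samples, extent %.2f x %.2f x %.2f mm, %d landmark pair(s)\n",
              nrow(x$points), diff(range(x$points[, 1])),
              diff(range(x$points[, 2])), diff(range(x$points[, 3])),
              length(x$landmarks)))
  invisible(x)
}

#' Convert a specimen's surface samples to a 3D model
#'
#' Bridges the twin and the measurement stage: the specimen's point samples
#' (in local mm coordinates) become a [model3d()] point cloud that can be
#' written to ASCII PLY with [write_ply()], perturbed, rescaled and measured
#' like any externally reconstructed model.
#'
#' @param specimen a `synthetic_specimen`.
#' @return A [model3d()] with `unit_scale = 1` (coordinates already in mm).
#' @export
specimen_model <- function(specimen) {
  stopifnot(inherits(specimen, "synthetic_specimen"))
  model3d(specimen$points)
}

#' Place a specimen at a world position
#'
#' @param specimen a `synthetic_specimen`.
#' @param at numeric length-3 world position (mm) for the specimen's local
#'   origin, typically the orbit aiming point.
#' @return The specimen with its `origin` set.
#' @export
place_specimen <- function(specimen, at) {
  stopifnot(inherits(specimen, "synthetic_specimen"))
  specimen$origin <- as.numeric(at)
  specimen
}

#' Render one frame of the digital twin
#'
#' Deterministic forward image formation: specimen surface samples are
#' projected at fixed magnification onto the sensor, grouped by depth offset
#' from the focal plane, blurred with a Gaussian kernel of sigma equal to the
#' linear defocus radius of the group, and composited far-to-near over the
#' uniform background. The focal plane sits `focus_distance_mm - c_pos_mm`
#' from the camera along the optical axis, so stepping the stacking axis
#' sweeps focus through the specimen without changing magnification or
#' framing.
#'
#' @param specimen a `synthetic_specimen` (see [generate_specimen()]).
#' @param cam_pose a [camera_pose()] aimed at the specimen.
#' @param model a [camera_model()].
#' @param c_pos_mm stacking-axis position, mm.
#' @param lateral_offset_px optional length-2 translational jitter (px) applied
#'   to the projection, for stress-testing fusion's no-registration assumption.
#' @return An [new_frame()] object (grayscale, values in `[0, 1]`).
#' @export
render_frame <- function(specimen, cam_pose, model, c_pos_mm = 0,
                         lateral_offset_px = c(0, 0)) {
  stopifnot(inherits(specimen, "synthetic_specimen"),
            inherits(cam_pose, "camera_pose"),
            inherits(model, "camera_model"))
  if (nrow(specimen$points) == 0L) stop("empty specimen")
  W <- model$sensor_px[1]; H <- model$sensor_px[2]
  d <- cam_pose$view_direction
  up <- if (abs(d[3]) > 1 - 1e-9) c(1, 0, 0) else c(0, 0, 1)
  right <- c(d[2] * up[3] - d[3] * up[2],
             d[3] * up[1] - d[1] * up[3],
             d[1] * up[2] - d[2] * up[1])
  right <- right / sqrt(sum(right^2))
  vup <- c(right[2] * d[3] - right[3] * d[2],
           right[3] * d[1] - right[1] * d[3],
           right[1] * d[2] - right[2] * d[1])

  P <- sweep(specimen$points, 2L, specimen$origin, "+")
  delta <- sweep(P, 2L, cam_pose$position, "-")
  depth <- as.vector(delta %*% d)
  u <- as.vector(delta %*% right)
  v <- as.vector(delta %*% vup)
  ix <- round((W + 1) / 2 + u / model$mm_per_px + lateral_offset_px[1])
  iy <- round((H + 1) / 2 - v / model$mm_per_px + lateral_offset_px[2])
  keep <- ix >= 1 & ix <= W & iy >= 1 & iy <= H & depth > 0
  out <- matrix(specimen$background, H, W)
  if (!any(keep))
    return(new_frame(out, c_pos_mm = c_pos_mm))

  focal <- model$focus_distance_mm - c_pos_mm
  offset <- depth[keep] - focal
  ix <- ix[keep]; iy <- iy[keep]
  inten <- specimen$intensity[keep]
  gain <- model$blur_gain_px_per_mm
  # group samples into depth slabs sharing one blur width (quantized to 1 px,
  # capped: far out-of-focus content is mush either way), signed so near and
  # far sides of the focal plane composite in the right order
  # blur-level ladder: fine steps near focus, geometric far from it, so far
  # content is properly washed out without exploding the slab count
  ladder <- c(0, 1.5, 3, 4.5, 6, 9, 13, 19, 28, 40)
  sig_idx <- if (gain > 0)
    findInterval(gain * abs(offset), (ladder[-1] + ladder[-10]) / 2) + 1L
  else rep(1L, length(offset))
  bin <- sign(offset) * sig_idx
  idx <- (ix - 1L) * H + iy
  grp <- split(seq_along(idx), bin)
  means <- vapply(grp, function(s) mean(offset[s]), 0)
  for (bn in names(grp)[order(-means)]) {  # far slabs first
    sel <- grp[[bn]]
    cnt <- matrix(0, H, W); val <- matrix(0, H, W)
    agg <- rowsum(cbind(1, inten[sel]), group = idx[sel])
    at <- as.integer(rownames(agg))
    cnt[at] <- agg[, 1]; val[at] <- agg[, 2]
    sigma <- ladder[max(1L, abs(as.integer(bn)))]  # bin 0 sits at the focal plane
    if (sigma > 0.05) {
      cnt <- approx_gauss_blur(cnt, sigma)
      val <- approx_gauss_blur(val, sigma)
    }
    alpha <- pmin(1, cnt)
    out <- out * (1 - alpha) + (val / pmax(cnt, 1e-8)) * alpha
  }
  new_frame(pmin(pmax(out, 0), 1), c_pos_mm = c_pos_mm)
}
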