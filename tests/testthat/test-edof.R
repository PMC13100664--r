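test_that("local sharpness maps are zero on uniform frames and deterministic", {
  u <- matrix(0.4, 40, 40)
  m <- local_sharpness_map(u, 9)
  expect_true(all(m == 0))
  f <- checker_frame(40, 40)
  expect_identical(local_sharpness_map(f, 9), local_sharpness_map(f, 9))
  expect_true(all(local_sharpness_map(f, 9) >= 0))
  expect_error(local_sharpness_map(f, 8), "odd")
  expect_error(local_sharpness_map(f, 41), "odd|smaller")
})

test_that("blurring never increases local sharpness away from boundaries", {
  set.seed(4)
  f <- matrix(runif(60 * 60), 60, 60)
  fb <- as.matrix(EBImage::gblur(f, 2))
  m0 <- local_sharpness_map(f, 9)
  mb <- local_sharpness_map(fb, 9)
  core <- 10:50
  expect_true(all(mb[core, core] <= m0[core, core] + 1e-12))
})

test_that("constant stacks fuse to the frame itself with index-zero tie-break", {
  f <- checker_frame(32, 32)
  st <- list(new_frame(f, c_pos_mm = 0), new_frame(f, c_pos_mm = 1),
             new_frame(f, c_pos_mm = 2))
  res <- fuse_stack(st, window_px = 5)
  expect_equal(res$image, f)
  # textured pixels tie across identical frames -> lowest index wins
  expect_true(all(res$depth_index[res$depth_index >= 0] == 0L))
})

test_that("single-frame stacks are returned unchanged", {
  f <- checker_frame(20, 20)
  res <- fuse_stack(list(new_frame(f, c_pos_mm = 3)), window_px = 5)
  expect_identical(res$image, f)
  expect_true(all(res$depth_index == 0L))
})

test_that("dimension mismatches are rejected", {
  expect_error(fuse_stack(list(new_frame(matrix(0, 10, 10)),
                               new_frame(matrix(0, 12, 10)))),
               "identical dimensions")
})

test_that("untextured background takes the sentinel index and median frame value", {
  n <- 30
  mk <- function(v) {
    f <- matrix(v, n, n)
    f[10:20, 10:20] <- checker_frame(11, 11)
    f
  }
  st <- list(new_frame(mk(0.3), c_pos_mm = 0), new_frame(mk(0.5), c_pos_mm = 1),
             new_frame(mk(0.7), c_pos_mm = 2))
  res <- fuse_stack(st, window_px = 5)
  expect_equal(res$depth_index[1, 1], -1L)
  expect_equal(res$image[1, 1], 0.5)  # median frame's background
})

test_that("a two-plane twin stack fuses to the all-sharp rendering away from the seam", {
  aim <- c(400, 400, 400)
  sp <- two_plate_specimen(aim, sep_mm = 4)
  cm <- twin_camera()
  cam <- aimed_camera(aim = aim, radius = 150, a_deg = 0, b_deg = 0)
  c_mid <- cm$focus_distance_mm - 150
  cpos <- c_mid + seq(-3, 3, by = 0.5)
  frames <- lapply(cpos, function(cc) render_frame(sp, cam, cm, cc))
  for (k in seq_along(frames)) frames[[k]]$meta$c_pos_mm <- cpos[k]
  res <- fuse_stack(frames, window_px = 9)

  cm_sharp <- twin_camera(blur_gain = 0)
  truth <- render_frame(sp, cam, cm_sharp, c_mid)$pixels

  # exclude a seam band around the horizontal plate boundary and the window
  # margin at plate borders; compare where the truth shows texture
  H <- nrow(truth); W <- ncol(truth)
  seam <- abs(seq_len(H) - (H + 1) / 2) <= 9
  core <- !seam
  diffmap <- abs(res$image - truth)
  frac_close <- mean(diffmap[core, ] < 0.05)
  expect_gt(frac_close, 0.95)

  # fused image is globally at least as sharp as any single frame
  best_single <- max(vapply(frames, edge_sharpness, 0))
  expect_gte(edge_sharpness(res$image), best_single)

  # depth indices on unambiguous textured pixels match the correct plate:
  # near plate (top half) is sharpest at higher C, far plate at lower C
  idx <- res$depth_index
  top <- idx[1:(H / 2 - 12), ]
  bot <- idx[(H / 2 + 12):H, ]
  top_c <- res$c_positions_mm[top[top >= 0] + 1]
  bot_c <- res$c_positions_mm[bot[bot >= 0] + 1]
  expect_gt(mean(top_c), mean(bot_c))
})

test_that("depth from a two-plate stack recovers the separation within one C step", {
  aim <- c(400, 400, 400)
  sp <- two_plate_specimen(aim, sep_mm = 4)
  cm <- twin_camera()
  cam <- aimed_camera(aim = aim, radius = 150)
  c_mid <- cm$focus_distance_mm - 150
  cpos <- c_mid + seq(-3, 3, by = 0.5)
  frames <- lapply(cpos, function(cc) {
    f <- render_frame(sp, cam, cm, cc); f$meta$c_pos_mm <- cc; f
  })
  h <- depth_from_stack(frames, window_px = 9)
  H <- nrow(h)
  top <- h[1:(H / 2 - 12), ]
  bot <- h[(H / 2 + 12):H, ]
  sep <- abs(median(top, na.rm = TRUE) - median(bot, na.rm = TRUE))
  expect_lt(abs(sep - 4), 0.5 + 1e-9)

  # reversing the stack leaves recovered heights unchanged
  h_rev <- depth_from_stack(rev(frames), window_px = 9)
  sep_rev <- abs(median(h_rev[1:(H / 2 - 12), ], na.rm = TRUE) -
                 median(h_rev[(H / 2 + 12):H, ], na.rm = TRUE))
  expect_equal(sep_rev, sep, tolerance = 1e-12)

  expect_error(depth_from_stack(frames[1], window_px = 9), "two frames")
})

test_that("a flat plate yields a height map constant to one C step", {
  aim <- c(400, 400, 400)
  set.seed(9)
  pts <- plate_points(aim, 0, pitch_mm = 0.08)
  sp <- synthetic_specimen(pts, intensity = runif(nrow(pts), 0.2, 1))
  cm <- twin_camera()
  cam <- aimed_camera(aim = aim, radius = 150)
  c_mid <- cm$focus_distance_mm - 150
  cpos <- c_mid + seq(-2, 2, by = 0.5)
  frames <- lapply(cpos, function(cc) {
    f <- render_frame(sp, cam, cm, cc); f$meta$c_pos_mm <- cc; f
  })
  h <- depth_from_stack(frames, window_px = 9)
  hv <- h[!is.na(h)]
  expect_gt(length(hv), 1000)
  # nearly all textured pixels within one 0.5 mm step of the plate position
  q <- quantile(hv, c(0.005, 0.995))
  expect_lte(diff(q), 1.0 + 1e-9)
  expect_lt(abs(median(hv) - c_mid), 0.5 + 1e-9)
})

test_that("translational jitter between frames degrades the fusion seam", {
  aim <- c(400, 400, 400)
  sp <- two_plate_specimen(aim, sep_mm = 4)
  cm <- twin_camera()
  cam <- aimed_camera(aim = aim, radius = 150)
  c_mid <- cm$focus_distance_mm - 150
  cpos <- c_mid + seq(-3, 3, by = 1)
  truth <- render_frame(sp, cam, twin_camera(blur_gain = 0), c_mid)$pixels
  err_for <- function(jitter) {
    frames <- lapply(seq_along(cpos), function(k) {
      off <- if (jitter) c((k %% 3) - 1, (k %% 2)) * 2 else c(0, 0)
      f <- render_frame(sp, cam, cm, cpos[k], lateral_offset_px = off)
      f$meta$c_pos_mm <- cpos[k]; f
    })
    res <- fuse_stack(frames, window_px = 9)
    mean(abs(res$image - truth))
  }
  expect_gt(err_for(TRUE), err_for(FALSE))
})

test_that("EDOF outputs round-trip through the on-disk formats", {
  f0 <- checker_frame(24, 24); f1 <- matrix(0.3, 24, 24)
  st <- list(new_frame(f0, c_pos_mm = 1.5), new_frame(f1, c_pos_mm = 2.5))
  res <- fuse_stack(st, window_px = 5)
  dir <- withr::local_tempdir()
  paths <- write_edof(res, file.path(dir, "vp"))
  expect_true(all(file.exists(paths)))
  img <- tiff::readTIFF(paths[["image"]])
  expect_equal(dim(img), dim(res$image))
  expect_lt(max(abs(img - res$image)), 1 / 65534)
  idx <- round(tiff::readTIFF(paths[["depth_index"]]) * 65535) - 1L
  expect_equal(idx, res$depth_index, ignore_attr = TRUE)
  meta <- jsonlite::read_json(paths[["meta"]], simplifyVector = TRUE)
  expect_equal(meta$c_positions_mm, res$c_positions_mm)
})
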