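test_that("scale factors follow the two-landmark constraint arithmetic", {
  expect_equal(compute_scale(scale_constraint(c(0, 0, 0), c(10, 0, 0), 20)), 2)
  expect_equal(compute_scale(scale_constraint(c(1, 1, 1), c(1, 2, 1), 1)), 1)
  expect_error(scale_constraint(c(1, 1, 1), c(1, 1, 1), 5), "coincident")
  expect_error(scale_constraint(c(0, 0, 0), c(1, 0, 0), -2), "> 0")
})

test_that("scaling then measuring recovers the caliper distance exactly", {
  set.seed(17)
  pts <- matrix(runif(300, -5, 5), ncol = 3)
  la <- pts[1, ]; lb <- pts[2, ]
  known <- 37.25
  m <- model3d(pts)
  s <- compute_scale(scale_constraint(la, lb, known))
  m2 <- apply_scale(m, s)
  got <- measure_distance(m2, m2$points[1, ], m2$points[2, ])
  expect_equal(got, known, tolerance = 1e-12)
})

test_that("isotropic scaling multiplies all pairwise distances and updates unit scale", {
  set.seed(23)
  pts <- matrix(runif(150, 0, 10), ncol = 3)
  m <- model3d(pts)
  m2 <- apply_scale(m, 2)
  expect_equal(m2$unit_scale, 2)
  for (k in 1:50) {
    ij <- sample(nrow(pts), 2)
    d1 <- sqrt(sum((pts[ij[1], ] - pts[ij[2], ])^2))
    d2 <- sqrt(sum((m2$points[ij[1], ] - m2$points[ij[2], ])^2))
    expect_equal(d2, 2 * d1, tolerance = 1e-12)
  }
  expect_identical(apply_scale(m, 1)$points, m$points)
  expect_error(apply_scale(m, 0), "> 0")
})

test_that("mesh volume scales with the cube of the factor", {
  # unit cube fixture with outward-oriented triangles; signed-volume oracle
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 face (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = 1 face (+z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  signed_volume <- function(pts, faces) {
    s <- 0
    for (i in seq_len(nrow(faces))) {
      a <- pts[faces[i, 1], ]; b <- pts[faces[i, 2], ]; cc <- pts[faces[i, 3], ]
      s <- s + sum(a * c(b[2] * cc[3] - b[3] * cc[2],
                         b[3] * cc[1] - b[1] * cc[3],
                         b[1] * cc[2] - b[2] * cc[1])) / 6
    }
    abs(s)
  }
  m <- model3d(v, faces = f)
  expect_equal(signed_volume(m$points, m$faces), 1, tolerance = 1e-12)
  m3 <- apply_scale(m, 3)
  expect_equal(signed_volume(m3$points, m3$faces), 27, tolerance = 1e-9)
})

test_that("distance measurement handles closed-form cases", {
  m <- model3d(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(measure_distance(m, c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(measure_distance(m, c(0, 0, 0), c(1, 1, 1)), sqrt(3))
})

test_that("twin specimens serialize to PLY and read back unchanged", {
  sp <- generate_specimen(seed = 2, texture_density = 50)
  m <- specimen_model(sp)
  path <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, path)
  m2 <- read_ply(path)
  expect_equal(m2$points, sp$points, tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("twin landmark distances survive the full scale pipeline", {
  sp <- generate_specimen(seed = 12)
  # pretend reconstruction returned the specimen at an arbitrary unknown scale
  arb <- 0.3173
  pts <- sp$points * arb
  m <- model3d(pts)
  lm <- sp$landmarks$mount_bar
  s <- compute_scale(scale_constraint(lm$a * arb, lm$b * arb, lm$distance_mm))
  m2 <- apply_scale(m, s)
  for (other in sp$landmarks) {
    got <- measure_distance(m2, other$a * arb * s, other$b * arb * s)
    expect_equal(got, other$distance_mm, tolerance = 1e-9)
  }
})

test_that("error statistics match hand-computed values", {
  # single record: hand arithmetic of the stated formulas
  one <- error_stats(measurement_record("len", 10.1, 10.0))
  expect_equal(one$records$absolute_error_mm, 0.1, tolerance = 1e-12)
  expect_equal(one$records$relative_error_pct, 1.0, tolerance = 1e-12)
  expect_equal(one$mae_um, 100, tolerance = 1e-9)
  expect_equal(one$rmse_um, 100, tolerance = 1e-9)

  # three constructed records against a spreadsheet-style table:
  # errors: +0.05, -0.12, +0.30 mm; refs: 5, 8, 20 mm
  # rel%: 1.0, 1.5, 1.5 -> MAPE 4/3
  # MAE = (0.05+0.12+0.30)/3 ; RMSE = sqrt((0.0025+0.0144+0.09)/3)
  recs <- rbind(measurement_record("a", 5.05, 5),
                measurement_record("b", 7.88, 8),
                measurement_record("c", 20.30, 20))
  es <- error_stats(recs)
  expect_equal(es$records$absolute_error_mm, c(0.05, -0.12, 0.30),
               tolerance = 1e-12)
  expect_equal(es$mape_pct, (1.0 + 1.5 + 1.5) / 3, tolerance = 1e-12)
  expect_equal(es$mae_mm, 0.47 / 3, tolerance = 1e-12)
  expect_equal(es$rmse_mm, sqrt(0.1069 / 3), tolerance = 1e-12)
  expect_equal(es$mae_um, 1000 * es$mae_mm)

  # identical model and reference values give all-zero errors
  z <- error_stats(measurement_record("z", 4, 4))
  expect_equal(z$mape_pct, 0)
  expect_equal(z$rmse_mm, 0)

  expect_error(error_stats(data.frame()), "at least one")
  bad <- data.frame(name = "neg", model_value_mm = 1, reference_value_mm = -1)
  expect_error(error_stats(bad), "> 0")
})

test_that("RMSE is never below MAE, with equality for equal-magnitude errors", {
  set.seed(41)
  for (k in 1:25) {
    n <- sample(1:8, 1)
    refs <- runif(n, 1, 30)
    model <- refs + rnorm(n, 0, 0.2)
    model <- pmax(model, 0.01)
    es <- error_stats(data.frame(name = paste0("d", 1:n),
                                 model_value_mm = model,
                                 reference_value_mm = refs))
    expect_gte(es$rmse_mm + 1e-12, es$mae_mm)
  }
  eq <- error_stats(data.frame(name = c("a", "b"),
                               model_value_mm = c(10.2, 9.8),
                               reference_value_mm = c(10, 10)))
  expect_equal(eq$rmse_mm, eq$mae_mm, tolerance = 1e-12)
})

test_that("noise-perturbed models recover landmarks with errors that vanish as noise does", {
  sp <- generate_specimen(seed = 77)
  lms <- sp$landmarks
  mape_at <- function(sigma, rep_seed) {
    set.seed(rep_seed)
    recs <- NULL
    for (r in 1:8) {
      noise <- function(p) p + rnorm(3, 0, sigma)
      a1 <- noise(lms$mount_bar$a); b1 <- noise(lms$mount_bar$b)
      s <- compute_scale(scale_constraint(a1, b1, lms$mount_bar$distance_mm))
      for (nm in c("body_length", "body_depth")) {
        lm <- lms[[nm]]
        d <- s * sqrt(sum((noise(lm$a) - noise(lm$b))^2))
        recs <- rbind(recs, data.frame(name = nm, model_value_mm = d,
                                       reference_value_mm = lm$distance_mm))
      }
    }
    error_stats(recs)$mape_pct
  }
  m0 <- mape_at(0, 1)
  expect_equal(m0, 0, tolerance = 1e-9)
  ms <- vapply(seq_along(c(0.002, 0.01, 0.05, 0.2)), function(i)
    mape_at(c(0.002, 0.01, 0.05, 0.2)[i], 100 + i), 0)
  expect_true(all(diff(ms) > 0))
  expect_lt(ms[1], 0.5)  # sub-percent error at small noise
})

test_that("measurement CSV and summary JSON round trip", {
  dir <- withr::local_tempdir()
  csv_in <- file.path(dir, "records.csv")
  write.csv(rbind(measurement_record("a", 5.05, 5),
                  measurement_record("b", 7.88, 8)), csv_in, row.names = FALSE)
  recs <- read_measurements(csv_in)
  es <- error_stats(recs)
  out <- write_error_summary(es, csv_path = file.path(dir, "out.csv"),
                             json_path = file.path(dir, "out.json"))
  j <- jsonlite::read_json(file.path(dir, "out.json"), simplifyVector = TRUE)
  expect_equal(j$mape_pct, es$mape_pct)
  got <- read.csv(file.path(dir, "out.csv"))
  expect_equal(got$absolute_error_mm, es$records$absolute_error_mm)
})
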