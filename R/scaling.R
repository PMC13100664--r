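#' Reconstructed 3D model
#'
#' Point cloud or triangle mesh in arbitrary model units, as produced by an
#' external photogrammetric reconstruction. `unit_scale` records how many mm
#' one model unit represents (1 until a scale constraint is applied).
#'
#' @param points n x 3 numeric matrix of vertices.
#' @param faces optional m x 3 integer matrix of 1-based triangle indices.
#' @param unit_scale mm per model unit.
#' @return An object of class `model3d`.
#' @export
model3d <- function(points, faces = NULL, unit_scale = 1) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L || nrow(points) < 1L)
    stop("points must be a non-empty n x 3 numeric matrix")
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    if (ncol(faces) != 3L) stop("faces must be an m x 3 index matrix")
    if (any(faces < 1L) || any(faces > nrow(points)))
      stop("face indices out of range")
    storage.mode(faces) <- "integer"
  }
  if (!is.numeric(unit_scale) || unit_scale <= 0)
    stop("unit_scale must be > 0")
  structure(list(points = points, faces = faces, unit_scale = unit_scale,
                 vertex_extra = NULL, extra_elements = NULL,
                 comments = character()),
            class = "model3d")
}

#' @export
print.model3d <- function(x, ...) {
  cat(sprintf("3D model: %d vertices, %d faces, unit scale %g mm/unit\n",
              nrow(x$points), if (is.null(x$faces)) 0L else nrow(x$faces),
              x$unit_scale))
  invisible(x)
}

#' Two-landmark scale constraint
#'
#' The scale constraint of the workflow: two landmarks are marked on the
#' specimen mount in model coordinates, and the corresponding physical
#' distance is measured with digital calipers.
#'
#' @param landmark_a,landmark_b length-3 model-unit coordinates; must be
#'   distinct.
#' @param known_distance_mm caliper-measured physical distance, mm (> 0).
#' @return An object of class `scale_constraint`.
#' @export
scale_constraint <- function(landmark_a, landmark_b, known_distance_mm) {
  landmark_a <- as.numeric(landmark_a); landmark_b <- as.numeric(landmark_b)
  if (length(landmark_a) != 3L || length(landmark_b) != 3L)
    stop("landmarks must be length-3 coordinates")
  if (!is.numeric(known_distance_mm) || known_distance_mm <= 0)
    stop("known_distance_mm must be > 0")
  if (sqrt(sum((landmark_a - landmark_b)^2)) < 1e-12)
    stop("landmarks are coincident")
  structure(list(landmark_a = landmark_a, landmark_b = landmark_b,
                 known_distance_mm = known_distance_mm),
            class = "scale_constraint")
}

#' Compute the isotropic scale factor from a constraint
#'
#' @param constraint a [scale_constraint()].
#' @return Scale factor in mm per model unit:
#'   `known_distance_mm / |landmark_a - landmark_b|`.
#' @examples
#' compute_scale(scale_constraint(c(0, 0, 0), c(10, 0, 0), 20))  # 2
#' @export
compute_scale <- function(constraint) {
  stopifnot(inherits(constraint, "scale_constraint"))
  d <- sqrt(sum((constraint$landmark_a - constraint$landmark_b)^2))
  constraint$known_distance_mm / d
}

#' Apply an isotropic scale to a model
#'
#' Multiplies all vertex coordinates by `s` and updates the model's unit
#' scale; topology is untouched. A single scalar is used because the scale
#' constraint fixes exactly one distance.
#'
#' @param model a [model3d()].
#' @param s scale factor, > 0.
#' @return The scaled model.
#' @export
apply_scale <- function(model, s) {
  stopifnot(inherits(model, "model3d"))
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    stop("scale factor must be a single value > 0")
  model$points <- model$points * s
  model$unit_scale <- model$unit_scale * s
  model
}

#' Measure a 1D distance on a scaled model
#'
#' Euclidean distance between two picked points, in the model's current
#' units (mm once a scale constraint has been applied). Points are given as
#' explicit coordinates; interactive picking belongs to external viewers.
#'
#' @param model a [model3d()] (used to confirm a scale has been established).
#' @param p,q length-3 coordinates in the model's current frame.
#' @return Distance in mm.
#' @export
measure_distance <- function(model, p, q) {
  stopifnot(inherits(model, "model3d"))
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != 3L || length(q) != 3L)
    stop("p and q must be length-3 coordinates")
  sqrt(sum((p - q)^2))
}

#' One model-vs-reference measurement
#'
#' @param name label for the distance.
#' @param model_value_mm distance measured on the scaled 3D model, mm (> 0).
#' @param reference_value_mm independent reference measurement (e.g.
#'   calibrated microscope), mm (> 0).
#' @return One-row data frame usable with [error_stats()].
#' @export
measurement_record <- function(name, model_value_mm, reference_value_mm) {
  if (model_value_mm <= 0 || reference_value_mm <= 0)
    stop("measurements must be > 0")
  data.frame(name = name, model_value_mm = model_value_mm,
             reference_value_mm = reference_value_mm,
             stringsAsFactors = FALSE)
}

#' Validation error statistics for paired measurements
#'
#' For each record the signed absolute error is `model - reference` (mm) and
#' the relative error is `|model - reference| / reference * 100` (%), with the
#' reference treated as ground truth. Summaries are the unweighted mean
#' absolute percent error (MAPE), the mean absolute error (MAE) and the root
#' mean square error (RMSE), reported in both mm and micrometres.
#'
#' @param records data frame with columns `name`, `model_value_mm`,
#'   `reference_value_mm` (see [measurement_record()]); at least one row.
#' @return An object of class `error_summary` with the per-record table
#'   (`records`, gaining columns `absolute_error_mm` and `relative_error_pct`)
#'   and fields `mape_pct`, `mae_mm`, `mae_um`, `rmse_mm`, `rmse_um`, `n`.
#' @examples
#' error_stats(measurement_record("demo", 10.1, 10.0))
#' @export
error_stats <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 1L)
    stop("records must be a data frame with at least one row")
  need <- c("model_value_mm", "reference_value_mm")
  if (!all(need %in% names(records)))
    stop("records must have columns model_value_mm and reference_value_mm")
  if (any(records$reference_value_mm <= 0))
    stop("reference values must be > 0")
  abs_err <- records$model_value_mm - records$reference_value_mm
  rel_pct <- abs(abs_err) / records$reference_value_mm * 100
  records$absolute_error_mm <- abs_err
  records$relative_error_pct <- rel_pct
  mae <- mean(abs(abs_err))
  rmse <- sqrt(mean(abs_err^2))
  structure(list(records = records,
                 mape_pct = mean(rel_pct),
                 mae_mm = mae, mae_um = mae * 1000,
                 rmse_mm = rmse, rmse_um = rmse * 1000,
                 n = nrow(records)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("Measurement validation over %d distance(s):\n", x$n))
  for (i in seq_len(nrow(x$records)))
    cat(sprintf("  %-16s model %8.3f mm  ref %8.3f mm  error %+7.3f mm (%.3f%%)\n",
                x$records$name[i], x$records$model_value_mm[i],
                x$records$reference_value_mm[i],
                x$records$absolute_error_mm[i],
                x$records$relative_error_pct[i]))
  cat(sprintf("  MAPE %.3f%%   MAE %.1f um   RMSE %.1f um\n",
              x$mape_pct, x$mae_um, x$rmse_um))
  invisible(x)
}

#' Measurement session I/O
#'
#' `read_measurements()` reads a CSV of records (columns `name`,
#' `model_value_mm`, `reference_value_mm`); `write_error_summary()` writes an
#' [error_stats()] result as a per-record CSV plus a JSON summary.
#'
#' @param path CSV path.
#' @param summary an `error_summary`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return `read_measurements()`: a data frame; `write_error_summary()`: the
#'   paths invisibly.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "model_value_mm", "reference_value_mm")
  if (!all(need %in% names(df)))
    stop("measurement CSV must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname read_measurements
#' @export
write_error_summary <- function(summary, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(summary, "error_summary"))
  if (!is.null(csv_path))
    utils::write.csv(summary$records, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(n = summary$n, mape_pct = summary$mape_pct,
                              mae_mm = summary$mae_mm, mae_um = summary$mae_um,
                              rmse_mm = summary$rmse_mm,
                              rmse_um = summary$rmse_um),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}
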