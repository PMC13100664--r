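#' Read / write ASCII PLY models
#'
#' Minimal ASCII PLY v1.0 support for the measurement stage. The vertex
#' element must carry float properties `x`, `y`, `z`; additional vertex
#' properties, face lists and unknown elements are carried through opaquely
#' and re-emitted by `write_ply()` (vertex coordinates are rewritten from the
#' model, everything else verbatim). Binary PLY is not supported.
#'
#' @param path file path.
#' @param model a [model3d()].
#' @return `read_ply()` returns a [model3d()]; `write_ply()` returns `path`
#'   invisibly.
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  if (!grepl("^format\\s+ascii\\s+1\\.0", trimws(lines[2])))
    stop("only ASCII PLY 1.0 is supported")
  end <- which(trimws(lines) == "end_header")[1]
  if (is.na(end)) stop("PLY header has no end_header")
  header <- lines[seq_len(end)]
  body <- lines[seq.int(end + 1L, length.out = length(lines) - end)]
  body <- body[nzchar(trimws(body))]

  elements <- list()
  cur <- NULL
  comments <- character()
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "comment") comments <- c(comments, trimws(ln))
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character())
    } else if (tok[1] == "property" && !is.null(cur)) {
      cur$props <- c(cur$props, if (tok[2] == "list") "list" else tok[3])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop("PLY file has no vertex element")

  offset <- 0L
  chunks <- list()
  for (el in elements) {
    n <- el$count
    if (offset + n > length(body))
      stop(sprintf("PLY body truncated: element '%s' needs %d rows", el$name, n))
    chunks[[el$name]] <- body[seq.int(offset + 1L, length.out = n)]
    offset <- offset + n
  }

  vp <- elements$vertex$props
  need <- match(c("x", "y", "z"), vp)
  if (anyNA(need)) stop("vertex element must have x, y, z properties")
  vrows <- strsplit(trimws(chunks$vertex), "\\s+")
  vmat <- do.call(rbind, lapply(seq_along(vrows), function(i) {
    v <- suppressWarnings(as.numeric(vrows[[i]]))
    if (length(v) != length(vp) || anyNA(v))
      stop(sprintf("parse error in vertex row %d: '%s'", i, chunks$vertex[i]))
    v
  }))
  pts <- vmat[, need, drop = FALSE]
  extra_cols <- setdiff(seq_along(vp), need)

  faces <- NULL
  if (!is.null(chunks$face) && length(chunks$face)) {
    frows <- strsplit(trimws(chunks$face), "\\s+")
    tri <- lapply(frows, function(v) {
      v <- as.integer(v)
      if (v[1] == 3L) v[2:4] + 1L else NULL
    })
    tri <- tri[!vapply(tri, is.null, TRUE)]
    if (length(tri)) faces <- do.call(rbind, tri)
  }

  m <- model3d(pts, faces = faces)
  m$comments <- comments
  m$vertex_extra <- if (length(extra_cols))
    list(props = vp[extra_cols], values = vmat[, extra_cols, drop = FALSE],
         order = order(c(need, extra_cols))) else NULL
  m$extra_elements <- list(header = header, chunks = chunks,
                           vertex_props = vp)
  m
}

#' @rdname read_ply
#' @export
write_ply <- function(model, path) {
  stopifnot(inherits(model, "model3d"))
  pts <- model$points
  n <- nrow(pts)
  has_extra <- !is.null(model$extra_elements)
  con <- file(path, "w")
  on.exit(close(con))
  if (has_extra && length(model$extra_elements$header)) {
    # re-emit the original header (vertex count unchanged by scaling)
    writeLines(model$extra_elements$header, con)
  } else {
    nf <- if (is.null(model$faces)) 0L else nrow(model$faces)
    hdr <- c("ply", "format ascii 1.0",
             sprintf("comment unit_scale_mm %g", model$unit_scale),
             sprintf("element vertex %d", n),
             "property float x", "property float y", "property float z")
    if (nf > 0L)
      hdr <- c(hdr, sprintf("element face %d", nf),
               "property list uchar int vertex_indices")
    writeLines(c(hdr, "end_header"), con)
  }
  if (has_extra) {
    ve <- model$vertex_extra
    vp <- model$extra_elements$vertex_props
    xyz_at <- match(c("x", "y", "z"), vp)
    cols <- matrix("", n, length(vp))
    cols[, xyz_at] <- sprintf("%.9g", pts)
    if (!is.null(ve))
      cols[, setdiff(seq_along(vp), xyz_at)] <- sprintf("%.9g", ve$values)
    writeLines(apply(cols, 1L, paste, collapse = " "), con)
    for (nm in names(model$extra_elements$chunks))
      if (nm != "vertex") writeLines(model$extra_elements$chunks[[nm]], con)
  } else {
    writeLines(apply(matrix(sprintf("%.9g", pts), n), 1L, paste,
                     collapse = " "), con)
    if (!is.null(model$faces))
      writeLines(apply(model$faces - 1L, 1L,
                       function(f) paste(c(3L, f), collapse = " ")), con)
  }
  invisible(path)
}

#' Read / write minimal Wavefront OBJ models
#'
#' Accepts only `v x y z` vertex records and `f` face records (1-based
#' indices; `f v/vt/vn` forms are reduced to the vertex index, polygons are
#' fan-triangulated). Everything else is ignored on read; `write_obj()` emits
#' plain `v`/`f` records.
#'
#' @param path file path.
#' @param model a [model3d()].
#' @return `read_obj()` returns a [model3d()]; `write_obj()` returns `path`
#'   invisibly.
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  if (!length(vlines)) stop("OBJ file has no vertices: ", path)
  pts <- do.call(rbind, lapply(vlines, function(ln) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2:4]))
    if (anyNA(v)) stop("parse error in OBJ vertex: '", ln, "'")
    v
  }))
  flines <- grep("^f\\s", lines, value = TRUE)
  faces <- NULL
  if (length(flines)) {
    tris <- list()
    for (ln in flines) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]][-1]
      vi <- as.integer(vapply(strsplit(tok, "/", fixed = TRUE),
                              function(p) p[1], ""))
      for (k in seq_len(length(vi) - 2L))
        tris[[length(tris) + 1L]] <- c(vi[1], vi[k + 1L], vi[k + 2L])
    }
    faces <- do.call(rbind, tris)
  }
  model3d(pts, faces = faces)
}

#' @rdname read_obj
#' @export
write_obj <- function(model, path) {
  stopifnot(inherits(model, "model3d"))
  lines <- apply(model$points, 1L,
                 function(p) sprintf("v %.9g %.9g %.9g", p[1], p[2], p[3]))
  if (!is.null(model$faces))
    lines <- c(lines, apply(model$faces, 1L,
                            function(f) paste(c("f", f), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
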