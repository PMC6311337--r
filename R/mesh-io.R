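# Mesh and landmark file I/O.  STL (binary and ASCII) and ASCII PLY cover the
# export formats of the common segmentation tools; landmark sets travel as
# JSON.  STL carries no unit metadata, so a scale factor applied on load is
# the only unit control (all downstream quantities assume millimetres).

#' Read a surface mesh from STL or PLY
#'
#' @param path file path.
#' @param format `"auto"` (by extension and content), `"stl"` or `"ply"`.
#' @param scale multiply all coordinates on load (e.g. 10 for a mesh stored
#'   in centimetres); default 1 assumes millimetres.
#' @return a [surface_mesh()] with outward-oriented normals.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply"), scale = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  if (file.info(path)$size == 0) {
    stop("format error: empty file: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", ply = "ply",
                     stop("format error: cannot infer mesh format from '",
                          ext, "'", call. = FALSE))
  }
  mesh <- if (format == "stl") read_stl(path) else read_ply(path)
  if (scale != 1) mesh$vertices <- mesh$vertices * scale
  surface_mesh(mesh$vertices, mesh$faces)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80)
  if (length(head) < 80) stop("format error: truncated STL", call. = FALSE)
  # ASCII STL starts with "solid" and contains "facet"; binary may also start
  # with "solid", so check the triangle count against the file size.
  size <- file.info(path)$size
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  is_binary <- length(ntri) == 1 && !is.na(ntri) &&
    size == 84 + 50 * as.numeric(ntri)
  if (is_binary) {
    raw <- readBin(con, "raw", 50 * ntri)
    m <- matrix(raw, nrow = 50)
    vals <- readBin(as.vector(m[1:48, ]), "numeric", size = 4,
                    n = 12 * ntri, endian = "little")
    vals <- matrix(vals, ncol = 12, byrow = TRUE)
    verts <- matrix(t(vals[, 4:12, drop = FALSE]), ncol = 3, byrow = TRUE)
    faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
    return(weld_vertices(verts, faces))
  }
  txt <- readLines(path, warn = FALSE)
  if (!any(grepl("facet", txt, fixed = TRUE))) {
    stop("format error: not a valid STL file: ", path, call. = FALSE)
  }
  vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
    stop("format error: ASCII STL vertex count not a multiple of 3",
         call. = FALSE)
  }
  verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  weld_vertices(verts, faces)
}

# merge duplicated vertices (exact match after rounding to 1e-9 mm)
weld_vertices <- function(verts, faces) {
  key <- paste(round(verts[, 1], 9), round(verts[, 2], 9),
               round(verts[, 3], 9))
  uid <- match(key, unique(key))
  keep <- !duplicated(key)
  list(vertices = verts[keep, , drop = FALSE],
       faces = matrix(uid[faces], ncol = 3))
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0 || txt[1] != "ply") {
    stop("format error: not a PLY file: ", path, call. = FALSE)
  }
  if (!any(grepl("^format ascii", txt))) {
    stop("format error: only ASCII PLY is supported", call. = FALSE)
  }
  endh <- match("end_header", txt)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", txt, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", txt, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) {
    stop("format error: PLY header lacks vertex/face elements", call. = FALSE)
  }
  vl <- txt[(endh + 1):(endh + nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  fl <- txt[(endh + nv + 1):(endh + nv + nf)]
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop("format error: non-triangular PLY face",
                         call. = FALSE)
    x[2:4] + 1L
  }))
  list(vertices = verts, faces = faces)
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path output path; format inferred from the extension unless given.
#' @param format `"auto"`, `"stl"` (binary), `"stl_ascii"` or `"ply"` (ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "stl_ascii", "ply")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), stl = "stl", ply = "ply",
                     stop("cannot infer output format", call. = FALSE))
  }
  v <- mesh$vertices
  f <- mesh$faces
  if (format == "stl") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    fn <- face_normals(mesh)$unit
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(fn[i, ], v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])),
               con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else if (format == "stl_ascii") {
    fn <- face_normals(mesh)$unit
    lines <- c("solid mesh")
    tri <- character(nrow(f))
    for (i in seq_len(nrow(f))) {
      tri[i] <- paste0(
        sprintf("facet normal %.9g %.9g %.9g\nouter loop\n",
                fn[i, 1], fn[i, 2], fn[i, 3]),
        paste(sprintf("vertex %.9g %.9g %.9g",
                      v[f[i, 1:3], 1], v[f[i, 1:3], 2], v[f[i, 1:3], 3]),
              collapse = "\n"),
        "\nendloop\nendfacet")
    }
    writeLines(c(lines, tri, "endsolid mesh"), path)
  } else {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    vl <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
    fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    writeLines(c(hdr, vl, fl), path)
  }
  invisible(path)
}

landmark_fields_required <- c("brim", "tubercle_edge_m", "symphysis_lowest_O",
                              "symphysis_upper", "symphysis_lower",
                              "obturator_loop", "tubercle_apex")
landmark_fields_optional <- c("contralateral_tubercle_apex", "entry")

#' Construct a landmark set
#'
#' Named anatomical points and curves on (or, for the contralateral tubercle,
#' off) a hemipelvis mesh: the ordered pelvic-brim polyline, the outer-edge
#' curve m of the pubic tubercle, the lowest pubic-symphysis point O, the
#' symphysis upper/lower boundary points, the closed obturator-foramen loop
#' and the tubercle apex.
#'
#' @param ... named components; curves as n x 3 matrices, points as length-3
#'   vectors.  Required: `brim`, `tubercle_edge_m`, `symphysis_lowest_O`,
#'   `symphysis_upper`, `symphysis_lower`, `obturator_loop`, `tubercle_apex`.
#'   Optional: `contralateral_tubercle_apex`, `entry`.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(...) {
  ls <- list(...)
  if (length(ls) == 1 && is.list(ls[[1]]) && is.null(dim(ls[[1]]))) {
    ls <- ls[[1]]
  }
  missing <- setdiff(landmark_fields_required, names(ls))
  if (length(missing) > 0) {
    stop("schema error: missing landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  curves <- c("brim", "tubercle_edge_m", "obturator_loop")
  for (nm in names(ls)) {
    ls[[nm]] <- if (nm %in% curves) as_point_matrix(ls[[nm]])
    else as.numeric(ls[[nm]])
  }
  if (nrow(ls$brim) < 2) {
    stop("landmark error: brim must have at least 2 points", call. = FALSE)
  }
  loop <- ls$obturator_loop
  if (vnorm(loop[1, ] - loop[nrow(loop), ]) > 1e-6) {
    stop("landmark error: obturator_loop is not closed", call. = FALSE)
  }
  structure(ls, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set with components:\n")
  for (nm in names(x)) {
    d <- dim(x[[nm]])
    cat(sprintf("  %-28s %s\n", nm,
                if (is.null(d)) "point" else sprintf("curve (%d points)", d[1])))
  }
  invisible(x)
}

# all on-surface landmark points as one matrix (contralateral point excluded:
# it lies on the other hemipelvis)
landmark_points_on_surface <- function(ls) {
  pts <- list()
  for (nm in setdiff(names(ls), "contralateral_tubercle_apex")) {
    pts[[nm]] <- as_point_matrix(ls[[nm]])
  }
  do.call(rbind, pts)
}

#' Check and snap a landmark set against its companion mesh
#'
#' Every landmark point (except the contralateral tubercle apex, which lies
#' on the opposite hemipelvis) must be within `tol` of the mesh surface;
#' points are snapped to their nearest surface point.
#'
#' @param ls a [landmark_set()].
#' @param mesh the companion [surface_mesh()].
#' @param tol off-surface tolerance in mm (default 1).
#' @return the snapped landmark set.
#' @export
snap_landmarks <- function(ls, mesh, tol = 1) {
  for (nm in setdiff(names(ls), "contralateral_tubercle_apex")) {
    p <- as_point_matrix(ls[[nm]])
    cp <- closest_on_mesh(mesh, p)
    d <- sqrt(rowSums((p - cp$points)^2))
    if (any(d > tol)) {
      stop(sprintf(
        "landmark error: '%s' lies %.2f mm off the mesh surface (tol %.1f)",
        nm, max(d), tol), call. = FALSE)
    }
    snapped <- cp$points
    ls[[nm]] <- if (is.null(dim(ls[[nm]]))) as.numeric(snapped[1, ]) else snapped
  }
  ls
}

#' Read / write a landmark set as JSON
#'
#' @param path JSON file with one key per landmark, each a point `[x,y,z]` or
#'   a list of points; coordinates in mm.
#' @param mesh optional companion mesh; when given, landmarks are checked to
#'   be within `tol` mm of the surface and snapped onto it.
#' @param tol off-surface tolerance in mm.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path, mesh = NULL, tol = 1) {
  if (!file.exists(path)) {
    stop("landmark file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  ls <- landmark_set(raw)
  if (!is.null(mesh)) ls <- snap_landmarks(ls, mesh, tol = tol)
  ls
}

#' @rdname read_landmarks
#' @param ls a [landmark_set()] to write.
#' @export
write_landmarks <- function(ls, path) {
  out <- lapply(unclass(ls), function(x) {
    if (is.null(dim(x))) as.numeric(x) else unname(x)
  })
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
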