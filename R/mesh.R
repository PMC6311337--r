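#' Triangulated bone surface mesh
#'
#' A `surface_mesh` is the geometric substrate of every corridor computation:
#' a triangulated, consistently wound surface in millimetres.  Corridor
#' stages require the mesh to be watertight (every edge shared by exactly two
#' faces) so that inside/outside queries are well defined.
#'
#' @param vertices numeric matrix, one vertex per row (x, y, z in mm).
#' @param faces integer matrix, one triangle per row, 1-based vertex indices.
#' @param orient logical; re-orient face winding so normals point outward
#'   (positive enclosed volume) when the mesh is closed and consistent.
#' @return an object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @export
surface_mesh <- function(vertices, faces, orient = TRUE) {
  vertices <- as_point_matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(vertices) == 0 || nrow(faces) == 0) {
    stop("empty geometry: mesh has no vertices or faces", call. = FALSE)
  }
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "surface_mesh")
  if (orient) m <- orient_outward(m)
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  list(unit = n / pmax(len, 1e-300), area = len / 2)
}

face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem; positive for outward winding.
#'
#' @param mesh a [surface_mesh()].
#' @return volume in mm^3 (signed).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
        a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
        a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

orient_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  }
  mesh
}

# edge incidence table: each undirected edge with counts and direction balance
edge_incidence <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  a <- pmin(he[, 1], he[, 2])
  b <- pmax(he[, 1], he[, 2])
  key <- paste(a, b)
  fwd <- he[, 1] < he[, 2]
  cnt <- table(key)
  bal <- tapply(ifelse(fwd, 1L, -1L), key, sum)
  list(count = cnt, balance = bal)
}

#' Validate a surface mesh
#'
#' Checks the geometric preconditions that the corridor stages rely on:
#' watertightness (every edge shared by exactly two faces), consistent
#' winding, absence of degenerate (zero-area) triangles and a plausible
#' millimetre bounding box.  Reports all violations rather than raising.
#'
#' @param mesh a [surface_mesh()].
#' @return list with `watertight`, `consistent_winding`, `n_open_edges`,
#'   `n_degenerate_faces`, `bbox` (2 x 3 matrix), `bbox_diag_mm`, `ok`
#'   (all checks passed) and a character vector `failures`.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  inc <- edge_incidence(mesh)
  open_edges <- sum(inc$count != 2L)
  winding_ok <- all(inc$count != 2L | abs(inc$balance) == 0L)
  fn <- face_normals(mesh)
  degen <- sum(fn$area < 1e-10)
  bb <- apply(mesh$vertices, 2, range)
  diag_mm <- sqrt(sum((bb[2, ] - bb[1, ])^2))
  failures <- character()
  if (open_edges > 0) {
    failures <- c(failures, sprintf(
      "not watertight: %d edges not shared by exactly 2 faces", open_edges))
  }
  if (!winding_ok) failures <- c(failures, "inconsistent face winding")
  if (degen > 0) {
    failures <- c(failures, sprintf("%d degenerate (zero-area) faces", degen))
  }
  if (diag_mm < 10 || diag_mm > 1000) {
    failures <- c(failures, sprintf(
      "bounding-box diagonal %.2f mm outside [10, 1000] (unit sanity)", diag_mm))
  }
  list(watertight = open_edges == 0L,
       consistent_winding = winding_ok,
       n_open_edges = open_edges,
       n_degenerate_faces = degen,
       bbox = bb,
       bbox_diag_mm = diag_mm,
       ok = length(failures) == 0L,
       failures = failures)
}

require_watertight <- function(mesh, stage) {
  rep <- validate_mesh(mesh)
  if (!rep$watertight) {
    stop(sprintf("%s requires a watertight mesh (%d open edges)",
                 stage, rep$n_open_edges), call. = FALSE)
  }
  invisible(TRUE)
}

# Cached spatial accelerator.  Rebuilt lazily; stored in an environment so a
# mesh passed around by value still reuses one accelerator per R session call
# chain.
mesh_accel <- function(mesh) {
  acc <- attr(mesh, "accel_env")
  if (is.null(acc)) {
    return(cpp_mesh_accel(mesh$vertices, mesh$faces))
  }
  if (is.null(acc$ptr)) acc$ptr <- cpp_mesh_accel(mesh$vertices, mesh$faces)
  acc$ptr
}

#' Attach a reusable spatial accelerator to a mesh
#'
#' Containment searches perform thousands of point-in-mesh queries; calling
#' this once per mesh lets all of them share one spatial grid.
#'
#' @param mesh a [surface_mesh()].
#' @return the mesh with an internal accelerator attached.
#' @export
mesh_with_accel <- function(mesh) {
  e <- new.env(parent = emptyenv())
  e$ptr <- cpp_mesh_accel(mesh$vertices, mesh$faces)
  attr(mesh, "accel_env") <- e
  mesh
}

# cached per-mesh face normals/areas/centroids (computed once per accel env)
mesh_geom <- function(mesh) {
  acc <- attr(mesh, "accel_env")
  if (!is.null(acc) && !is.null(acc$geom)) return(acc$geom)
  fn <- face_normals(mesh)
  g <- list(unit = fn$unit, area = fn$area, centroids = face_centroids(mesh))
  if (!is.null(acc)) acc$geom <- g
  g
}

# Outward normal averaged over the faces that touch the radius-ball around
# p (centroid or any vertex within radius), area weighted; falls back to the
# nearest face normal.  Vertex inclusion matters on meshes whose faces are
# larger than the patch radius.
patch_normal <- function(mesh, p, radius = 2) {
  g <- mesh_geom(mesh)
  d <- cpp_point_face_dists(mesh_accel(mesh), as.numeric(p))
  sel <- d <= radius
  if (!any(sel)) sel <- which.min(d)
  # cap the weight of faces much larger than the patch: only the ball-sized
  # piece of a large face is local evidence
  w <- pmin(g$area[sel], pi * radius^2)
  n <- colSums(g$unit[sel, , drop = FALSE] * w)
  unitv(n)
}

# closest point(s) on the mesh surface; q is a point or n x 3 matrix
closest_on_mesh <- function(mesh, q) {
  q <- as_point_matrix(q)
  res <- cpp_closest_point(mesh_accel(mesh), q)
  list(points = res[, 1:3, drop = FALSE], faces = as.integer(res[, 4]))
}

# rigid/reflection transform helper used throughout the tests
transform_points <- function(p, R = diag(3), t = c(0, 0, 0)) {
  p <- as_point_matrix(p)
  sweep(p %*% t(R), 2, -t)
}
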