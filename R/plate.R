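# Plate placement: the offset brim curve and the insertion sites S, M, L.

#' Reconstruction-plate specification
#'
#' Defaults describe the common 3.5 mm low-profile pelvic reconstruction
#' plate: 10 mm wide, 13 mm hole pitch, first hole 6.5 mm from the tip.
#'
#' @param width plate width (mm).
#' @param hole_pitch distance between screw holes (mm).
#' @param first_hole_offset distance from the plate tip to the first hole (mm).
#' @param screw_diameter screw diameter (mm).
#' @return a `plate_spec` list.
#' @export
plate_spec <- function(width = 10, hole_pitch = 13, first_hole_offset = 6.5,
                       screw_diameter = 3.5) {
  vals <- c(width, hole_pitch, first_hole_offset, screw_diameter)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("parameter error: plate dimensions must be positive", call. = FALSE)
  }
  structure(list(width = width, hole_pitch = hole_pitch,
                 first_hole_offset = first_hole_offset,
                 screw_diameter = screw_diameter), class = "plate_spec")
}

#' Offset the pelvic-brim curve across the superior surface
#'
#' Constructs the curve at geodesic surface distance `offset` from the brim,
#' displaced into the superior pubic surface along which the plate is laid:
#' each brim station is marched across the surface in
#' the tangent plane, re-projecting onto the mesh after every step, until the
#' accumulated surface distance reaches `offset`.  On a planar face this
#' reduces to the exact Euclidean offset.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param brim ordered on-surface polyline (medial to lateral), n x 3.
#' @param offset surface distance in mm (default 5).
#' @param side_hint an on-surface point on the desired side of the brim
#'   (e.g. the midpoint of the tubercle edge curve); used to disambiguate the
#'   two possible offset directions in a reflection-safe way.
#' @param step marching step (mm).
#' @return n x 3 matrix of on-surface offset points, ordering preserved.
#' @export
offset_brim_curve <- function(mesh, brim, offset = 5, side_hint = NULL,
                              step = 0.5) {
  brim <- as_point_matrix(brim)
  if (offset < 0) stop("offset must be >= 0", call. = FALSE)
  if (offset == 0) return(brim)
  n <- nrow(brim)
  if (n < 2) stop("brim needs at least 2 points", call. = FALSE)
  tangents <- brim[pmin(seq_len(n) + 1, n), , drop = FALSE] -
    brim[pmax(seq_len(n) - 1, 1), , drop = FALSE]
  out <- matrix(NA_real_, n, 3)
  hint_normal <- if (!is.null(side_hint)) patch_normal(mesh, side_hint) else NULL
  # decide the side once, at the mid station (typically the flattest)
  mid <- ceiling(n / 2)
  tv_mid <- unitv(tangents[mid, ])
  nv_mid <- patch_normal(mesh, brim[mid, ], radius = 2)
  d_mid <- unitv(cross3(nv_mid, tv_mid))
  sign_choice <- choose_offset_side(mesh, brim[mid, ], d_mid, offset, step,
                                    side_hint, hint_normal)
  for (i in seq_len(n)) {
    tv <- unitv(tangents[i, ])
    nv <- patch_normal(mesh, brim[i, ], radius = 2)
    d0 <- cross3(nv, tv)
    if (vnorm(d0) < 1e-8) {
      stop(sprintf("geometry error: degenerate tangent at brim station %d", i),
           call. = FALSE)
    }
    d0 <- unitv(d0)
    out[i, ] <- march_offset(mesh, brim[i, ], sign_choice * d0, offset, step,
                             station = i)
  }
  out
}

# Try both directions at the reference station and pick the one whose
# landing surface patch matches the hint point's surface sheet.  If neither
# direction stays on that sheet the requested offset does not fit on the
# hinted surface.
choose_offset_side <- function(mesh, p0, d0, offset, step, side_hint,
                               hint_normal) {
  if (is.null(side_hint)) return(1)
  score <- function(s) {
    q <- tryCatch(march_offset(mesh, p0, s * d0, offset, step, station = 1),
                  error = function(e) NULL)
    if (is.null(q)) return(-Inf)
    nq <- patch_normal(mesh, q, radius = 2)
    align <- sum(nq * hint_normal)
    # tie-break on proximity to the hint point (scaled to stay secondary)
    align - 1e-3 * vnorm(q - side_hint)
  }
  s1 <- score(1)
  s2 <- score(-1)
  if (max(s1, s2) < 0.3) {
    stop(sprintf(
      "geometry error: offset %g mm falls off the hinted surface sheet",
      offset), call. = FALSE)
  }
  if (s1 >= s2) 1 else -1
}

march_offset <- function(mesh, p0, d, offset, step, station) {
  p <- p0
  n_ref <- NULL  # set from the first face reached: the surface sheet marched
  remaining <- offset
  guard <- 0
  while (remaining > 1e-9) {
    st <- min(step, remaining)
    cp <- closest_on_mesh(mesh, p + st * d)
    q <- cp$points[1, ]
    adv <- vnorm(q - p)
    if (adv < 1e-7) {
      stop(sprintf("geometry error: offset curve stalls at brim station %d",
                   station), call. = FALSE)
    }
    nq <- mesh_geom(mesh)$unit[cp$faces[1], ]
    if (is.null(n_ref)) n_ref <- nq
    if (vangle(nq, n_ref) > 60) {
      stop(sprintf(
        "geometry error: offset %g mm falls off the surface at brim station %d",
        offset, station), call. = FALSE)
    }
    d_new <- project_to_plane(d, nq)
    if (vnorm(d_new) < 1e-8) {
      stop(sprintf("geometry error: offset direction degenerates at station %d",
                   station), call. = FALSE)
    }
    d <- unitv(d_new)
    p <- q
    remaining <- remaining - adv
    guard <- guard + 1
    if (guard > 1000) {
      stop(sprintf("geometry error: offset march fails to converge at station %d",
                   station), call. = FALSE)
    }
  }
  p
}

#' Locate the insertion points S, M and L on the offset curve
#'
#' S is the (most medial) crossing of the offset curve with the outer-edge
#' curve of the pubic tubercle; M and L sit at the plate's first and second
#' hole arc distances lateral of S along the offset curve.  "Lateral" is the
#' direction of increasing distance from the lowest symphysis point O.
#'
#' @param mesh the companion [surface_mesh()] (unused geometrically, kept for
#'   interface symmetry and future re-projection).
#' @param offset_curve on-surface polyline from [offset_brim_curve()].
#' @param tubercle_edge_m on-surface curve crossing the offset curve.
#' @param plate a [plate_spec()].
#' @param O lowest pubic-symphysis point (orients the lateral direction).
#' @param max_gap largest curve-to-curve distance still accepted as a
#'   crossing (mm).
#' @return list with `S`, `M`, `L`, `offset_curve`, `arc_S`.
#' @export
locate_insertion_points <- function(mesh, offset_curve, tubercle_edge_m,
                                    plate = plate_spec(), O = NULL,
                                    max_gap = 1) {
  oc <- as_point_matrix(offset_curve)
  mcurve <- as_point_matrix(tubercle_edge_m)
  if (!is.null(O)) {
    if (vnorm(oc[1, ] - O) > vnorm(oc[nrow(oc), ] - O)) {
      oc <- oc[rev(seq_len(nrow(oc))), , drop = FALSE]
    }
  }
  # coarse scan first, then 0.05 mm resampling near the approach region
  occ <- polyline_resample(oc, 1)
  dc <- vapply(seq_len(nrow(occ)), function(i) {
    polyline_nearest(mcurve, occ[i, ])$dist
  }, numeric(1))
  if (min(dc) > max_gap + 2) {
    stop(sprintf(
      "no-intersection error: tubercle edge is %.2f mm from the offset curve",
      min(dc)), call. = FALSE)
  }
  ocf <- polyline_resample(oc, 0.05)
  s_ocf <- polyline_arclength(ocf)
  sc_ <- polyline_arclength(occ)
  arc_near <- sc_[which.min(dc)]
  near <- abs(s_ocf - arc_near) <= 4
  d <- rep(Inf, nrow(ocf))
  d[near] <- vapply(which(near), function(i) {
    polyline_nearest(mcurve, ocf[i, ])$dist
  }, numeric(1))
  hit <- which(d <= max_gap)
  if (length(hit) == 0) {
    stop(sprintf(
      "no-intersection error: tubercle edge is %.2f mm from the offset curve",
      min(d)), call. = FALSE)
  }
  # within the first contiguous run of near stations, take the local minimum
  run_end <- hit[1]
  while (run_end + 1 <= nrow(ocf) && d[run_end + 1] <= max_gap) {
    run_end <- run_end + 1
  }
  run <- hit[1]:run_end
  iS <- run[which.min(d[run])]
  arc_S <- s_ocf[iS]
  S <- ocf[iS, ]
  arc_M <- arc_S + plate$first_hole_offset
  arc_L <- arc_S + plate$first_hole_offset + plate$hole_pitch
  total <- s_ocf[length(s_ocf)]
  if (arc_L > total + 1e-9) {
    stop(sprintf(
      "curve-too-short error: need %.1f mm beyond S but only %.1f mm available",
      plate$first_hole_offset + plate$hole_pitch, total - arc_S),
      call. = FALSE)
  }
  M <- polyline_point_at(ocf, s_ocf, arc_M)
  L <- polyline_point_at(ocf, s_ocf, arc_L)
  list(S = S, M = M, L = L, offset_curve = oc, arc_S = arc_S)
}
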