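# Corridor analysis: cylinder-in-mesh containment, the obturator-tangential
# screw, cross-section measuring planes, maximal inclination searches, screw
# lengths and the safe-region pattern.

#' Corridor search configuration
#'
#' Numerical parameters of the containment searches.  All defaults are in
#' millimetres and degrees.
#'
#' @param offset brim-to-plate offset (mm).
#' @param plate a [plate_spec()].
#' @param diameter screw diameter (mm).
#' @param min_length minimum implantable screw length (mm).
#' @param tol containment tolerance: sample points may sit up to `tol`
#'   outside the surface (mm).
#' @param ang_tol angular bisection tolerance (deg).
#' @param len_tol screw-length bisection tolerance (mm).
#' @param entry_band sample points less than this far below the entry tangent
#'   plane are exempt from the inside test (the not-yet-inserted screw
#'   portion) (mm).
#' @param apex_threshold safe-region apex angle separating blunt from sharp
#'   V patterns (deg).
#' @param n_axial,n_circ,n_cap cylinder sampling densities.
#' @param max_tilt largest tilt considered by the angle searches (deg).
#' @param coarse_step coarse bracketing step of the angle searches (deg).
#' @param psi_range medial-tilt search range of the tangential screw (deg;
#'   negative = lateral).
#' @param tangential_min_length length the tangential screw must reach for a
#'   direction to count as staying within the bone (mm); directions whose
#'   contained length is shorter (because they breach into the obturator)
#'   are infeasible.
#' @param phi_halfwidth anterior/posterior sweep half-width of the tangential
#'   search (deg).
#' @param phi_step anterior/posterior sweep step (deg).
#' @param measures which measurement blocks [analyze_hemipelvis()] runs.
#' @return a `corridor_config` list.
#' @export
corridor_config <- function(offset = 5, plate = plate_spec(), diameter = 3.5,
                            min_length = 14, tol = 0.05, ang_tol = 0.05,
                            len_tol = 0.01, entry_band = 0.5,
                            apex_threshold = 90, n_axial = 64, n_circ = 16,
                            n_cap = 16, max_tilt = 89, coarse_step = 1,
                            psi_range = c(-45, 80), phi_halfwidth = 24,
                            phi_step = 3, tangential_min_length = 35,
                            measures = c("inner", "outer", "tangential",
                                         "region", "morphometrics")) {
  stopifnot(tol > 0, ang_tol > 0, len_tol > 0, min_length >= 0,
            entry_band >= 0, diameter > 0)
  structure(list(offset = offset, plate = plate, diameter = diameter,
                 min_length = min_length, tol = tol, ang_tol = ang_tol,
                 len_tol = len_tol, entry_band = entry_band,
                 apex_threshold = apex_threshold, n_axial = n_axial,
                 n_circ = n_circ, n_cap = n_cap, max_tilt = max_tilt,
                 coarse_step = coarse_step, psi_range = psi_range,
                 phi_halfwidth = phi_halfwidth, phi_step = phi_step,
                 tangential_min_length = tangential_min_length,
                 measures = measures),
            class = "corridor_config")
}

#' Virtual screw cylinder
#'
#' @param entry entry point (mm).
#' @param axis unit tip direction.
#' @param diameter screw diameter (mm, default 3.5).
#' @param length screw length (mm).
#' @return a `screw_cylinder`.
#' @export
screw_cylinder <- function(entry, axis, diameter = 3.5, length = 14) {
  axis <- as.numeric(axis)
  if (abs(vnorm(axis) - 1) > 1e-9) axis <- unitv(axis)
  if (diameter <= 0 || length <= 0) {
    stop("parameter error: screw diameter and length must be positive",
         call. = FALSE)
  }
  structure(list(entry = as.numeric(entry), axis = axis,
                 diameter = diameter, length = length),
            class = "screw_cylinder")
}

# Sample points on the lateral surface and tip cap of a cylinder.  When an
# `align` direction is given, the circumferential sampling places a sample
# exactly at +-align (projected), so the extreme points along the sensitive
# direction of a search are sampled without angular quantisation error.
cylinder_samples <- function(cyl, n_axial = 64, n_circ = 16, n_cap = 16,
                             align = NULL, axial_pitch = NULL) {
  r <- cyl$diameter / 2
  b <- plane_basis(cyl$axis)
  stagger <- TRUE
  if (!is.null(align)) {
    e1 <- project_to_plane(align, cyl$axis)
    if (vnorm(e1) > 1e-8) {
      b <- list(e1 = unitv(e1), e2 = cross3(cyl$axis, unitv(e1)))
      # keep every ring sampling the exact +-align extremes
      stagger <- FALSE
    }
  }
  tj <- if (is.null(axial_pitch)) {
    seq(0, cyl$length, length.out = n_axial)
  } else {
    # fixed-pitch stations: sample positions do not shift with the candidate
    # length, so containment is monotone in length during bisection
    unique(c(seq(0, cyl$length, by = axial_pitch), cyl$length))
  }
  n_axial <- length(tj)
  ang0 <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  pts <- matrix(NA_real_, n_axial * n_circ, 3)
  k <- 1
  for (j in seq_len(n_axial)) {
    # stagger alternate rings for better angular coverage
    ang <- ang0 + if (stagger) (j %% 2) * pi / n_circ else 0
    ring <- outer(cos(ang), b$e1) + outer(sin(ang), b$e2)
    pts[k:(k + n_circ - 1), ] <-
      matrix(cyl$entry, n_circ, 3, byrow = TRUE) + r * ring +
      tj[j] * matrix(cyl$axis, n_circ, 3, byrow = TRUE)
    k <- k + n_circ
  }
  tipc <- matrix(cyl$entry + cyl$length * cyl$axis, 1, 3)
  if (n_cap > 1) {
    n_in <- max(1, n_cap - 1)
    ang <- 2 * pi * (seq_len(n_in) - 1) / n_in
    ring <- outer(cos(ang), b$e1) + outer(sin(ang), b$e2)
    tipc <- rbind(tipc, matrix(tipc[1, ], n_in, 3, byrow = TRUE) +
                    0.6 * r * ring)
  }
  rbind(pts, tipc)
}

#' Test whether a screw cylinder is contained in the bone
#'
#' Samples the cylinder's lateral surface and tip cap and requires every
#' sample to lie inside the watertight mesh, allowing an excursion of up to
#' `tol` mm.  When `entry_normal` is supplied, samples less than
#' `entry_band` mm below the entry tangent plane are exempt (they belong to
#' the not-yet-inserted portion of the screw).
#'
#' @param mesh a watertight [surface_mesh()] (attach an accelerator with
#'   [mesh_with_accel()] when testing many cylinders).
#' @param cyl a [screw_cylinder()].
#' @param tol containment tolerance (mm).
#' @param entry_normal outward surface normal at the entry point, or `NULL`
#'   for no entry exemption.
#' @param entry_band exemption band below the entry plane (mm).
#' @param details also compute the signed clearance (slower).
#' @param n_axial,n_circ,n_cap sampling densities.
#' @return list with `contained`, `clearance` (signed mm, `NA` unless
#'   `details`), `n_tested`.
#' @export
contains_cylinder <- function(mesh, cyl, tol = 0.05, entry_normal = NULL,
                              entry_band = 0.5, details = FALSE,
                              n_axial = 64, n_circ = 16, n_cap = 16,
                              align = NULL, axial_pitch = NULL) {
  if (!isTRUE(attr(mesh, "watertight_checked"))) {
    require_watertight(mesh, "contains_cylinder")
  }
  pts <- cylinder_samples(cyl, n_axial, n_circ, n_cap, align = align,
                          axial_pitch = axial_pitch)
  if (!is.null(entry_normal)) {
    depth <- as.vector((pts - matrix(cyl$entry, nrow(pts), 3, byrow = TRUE)) %*%
                         unitv(entry_normal))
    pts <- pts[depth <= -entry_band, , drop = FALSE]
  }
  if (nrow(pts) == 0) {
    # every sample is above the entry plane: the screw never enters the bone
    return(list(contained = FALSE, clearance = NA_real_, n_tested = 0L))
  }
  acc <- mesh_accel(mesh)
  if (details) {
    sd_ <- cpp_signed_distance(acc, pts)
    cl <- min(sd_)
    list(contained = cl >= -tol, clearance = cl, n_tested = nrow(pts))
  } else {
    list(contained = cpp_all_inside_tol(acc, pts, tol),
         clearance = NA_real_, n_tested = nrow(pts))
  }
}

#' Maximal contained screw length along a fixed axis
#'
#' Bisection (to `len_tol` mm) for the longest cylinder from `entry` along
#' `axis` that remains contained.
#'
#' @param mesh watertight [surface_mesh()].
#' @param entry entry point on the surface.
#' @param axis unit tip direction.
#' @param config a [corridor_config()].
#' @param entry_normal outward normal at the entry (for the exemption band);
#'   estimated from the mesh when `NULL`.
#' @return maximal length (mm).
#' @export
screw_length <- function(mesh, entry, axis, config = corridor_config(),
                         entry_normal = NULL, align = NULL) {
  if (is.null(entry_normal)) entry_normal <- patch_normal(mesh, entry)
  pitch <- 2 * config$min_length / config$n_axial
  test_len <- function(L) {
    contains_cylinder(mesh, screw_cylinder(entry, axis, config$diameter, L),
                      tol = config$tol, entry_normal = entry_normal,
                      entry_band = config$entry_band,
                      n_axial = config$n_axial, n_circ = config$n_circ,
                      n_cap = config$n_cap, align = align,
                      axial_pitch = pitch)$contained
  }
  lo <- config$min_length
  if (!test_len(lo)) {
    stop(sprintf(
      "below-minimum error: no contained screw of length >= %.1f mm along this axis",
      config$min_length), call. = FALSE)
  }
  bb <- apply(mesh$vertices, 2, range)
  maxlen <- sqrt(sum((bb[2, ] - bb[1, ])^2)) + 1
  hi <- lo
  while (hi < maxlen && test_len(min(2 * hi, maxlen))) hi <- min(2 * hi, maxlen)
  if (hi >= maxlen) return(maxlen)
  hi <- min(2 * hi, maxlen)
  while (hi - lo > config$len_tol) {
    mid <- (lo + hi) / 2
    if (test_len(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Maximal inclination angle within a measuring plane
#'
#' Tilts the screw from the reference line within the measuring plane, in the
#' anterior or posterior sense, and finds (1 deg coarse bracket, then
#' bisection to `ang_tol`) the largest tilt at which the screw remains
#' contained.  Posterior results are reported negative.  Under both length
#' policies feasibility at a tilt means "a `min_length` screw fits"; the
#' policies differ in the screw that is reported: the fixed minimum-length
#' screw (posterior convention) or the maximal tangent-length screw at the
#' limiting angle (anterior convention).
#'
#' @param mesh watertight [surface_mesh()].
#' @param entry entry point on the surface.
#' @param plane_normal unit normal of the measuring plane.
#' @param reference_line unit in-plane reference direction (pointing into
#'   the bone).
#' @param sense `"anterior"` or `"posterior"`.
#' @param anterior_hint vector with a positive component along the anterior
#'   direction (resolves the in-plane tilt sense; reflection-safe when taken
#'   from the landmarks).
#' @param length_policy `"fixed-14"` or `"max-tangent"`.
#' @param config a [corridor_config()].
#' @param entry_normal outward normal at the entry.
#' @return list with `angle_deg` (signed), `bracket` (contained/violating
#'   tilt magnitudes), `screw` ([screw_cylinder()] at the contained bracket
#'   end), `capped` (search hit `max_tilt`).
#' @export
max_inclination_angle <- function(mesh, entry, plane_normal, reference_line,
                                  sense = c("anterior", "posterior"),
                                  anterior_hint,
                                  length_policy = c("fixed-14", "max-tangent"),
                                  config = corridor_config(),
                                  entry_normal = NULL) {
  sense <- match.arg(sense)
  length_policy <- match.arg(length_policy)
  if (is.null(entry_normal)) entry_normal <- patch_normal(mesh, entry)
  n <- unitv(plane_normal)
  r0 <- unitv(project_to_plane(reference_line, n))
  a_in <- project_to_plane(anterior_hint, n)
  a_in <- a_in - sum(a_in * r0) * r0
  if (vnorm(a_in) < 1e-8) {
    stop("geometry error: anterior hint is parallel to the reference line",
         call. = FALSE)
  }
  a_in <- unitv(a_in)
  tilt_dir <- if (sense == "anterior") a_in else -a_in
  axis_at <- function(theta) {
    th <- deg2rad(theta)
    cos(th) * r0 + sin(th) * tilt_dir
  }
  pitch <- 2 * config$min_length / config$n_axial
  feasible <- function(theta) {
    cyl <- screw_cylinder(entry, axis_at(theta), config$diameter,
                          config$min_length)
    contains_cylinder(mesh, cyl, tol = config$tol,
                      entry_normal = entry_normal,
                      entry_band = config$entry_band,
                      n_axial = config$n_axial, n_circ = config$n_circ,
                      n_cap = config$n_cap, align = tilt_dir,
                      axial_pitch = pitch)$contained
  }
  if (!feasible(0)) {
    stop("no-corridor error: screw not contained at the reference direction",
         call. = FALSE)
  }
  lo <- 0
  hi <- NA
  th <- config$coarse_step
  while (th <= config$max_tilt) {
    if (!feasible(th)) { hi <- th; break }
    lo <- th
    th <- th + config$coarse_step
  }
  capped <- is.na(hi)
  if (capped) {
    theta_star <- config$max_tilt
    lo <- config$max_tilt
    hi <- config$max_tilt
  } else {
    while (hi - lo > config$ang_tol) {
      mid <- (lo + hi) / 2
      if (feasible(mid)) lo <- mid else hi <- mid
    }
    theta_star <- (lo + hi) / 2
  }
  len <- if (length_policy == "fixed-14") config$min_length else {
    screw_length(mesh, entry, axis_at(lo), config, entry_normal,
                 align = tilt_dir)
  }
  screw <- screw_cylinder(entry, axis_at(lo), config$diameter, len)
  sgn <- if (sense == "anterior") 1 else -1
  list(angle_deg = sgn * theta_star, bracket = c(contained = lo, violated = hi),
       screw = screw, capped = capped)
}

#' The screw at the line tangential to the obturator
#'
#' From the outer insertion site L, finds the contained screw direction with
#' the minimal medial inclination (the most lateral direction that still
#' stays within the bone); in a hemipelvis with an obturator foramen this
#' direction is tangent to the foramen-side inner cortex.  The direction
#' family is parameterised by a medial tilt psi (from the inward reference
#' toward the symphysis) and an anterior/posterior tilt phi; for each psi a
#' sweep over phi decides feasibility, and psi is minimised by bisection.
#'
#' @param mesh watertight [surface_mesh()].
#' @param L outer insertion site on the surface.
#' @param O lowest symphysis point (defines the medial direction).
#' @param anterior_hint vector with a positive anterior component.
#' @param config a [corridor_config()].
#' @param entry_normal outward normal at L.
#' @return list with `screw` (at maximal tangent length `L0`), `L0`,
#'   `psi_deg` (medial tilt of the returned axis), `phi_deg`,
#'   `psi_bracket`, `capped` (no lateral bound found inside `psi_range`:
#'   no tangency constraint), `frame` (r, m, a unit vectors).
#' @export
tangential_obturator_screw <- function(mesh, L, O, anterior_hint,
                                       config = corridor_config(),
                                       entry_normal = NULL) {
  if (is.null(entry_normal)) entry_normal <- patch_normal(mesh, L)
  # the screw must traverse the corridor past the foramen; cap the required
  # length by the subject's own L-to-O extent so small bones stay feasible
  feas_len <- max(config$min_length,
                  min(config$tangential_min_length, 0.7 * vnorm(O - L)))
  r0 <- unitv(-entry_normal)
  mdir <- project_to_plane(O - L, r0)
  if (vnorm(mdir) < 1e-6) {
    stop("geometry error: symphysis point projects onto the entry normal",
         call. = FALSE)
  }
  mdir <- unitv(mdir)
  adir <- cross3(r0, mdir)
  if (sum(adir * anterior_hint) < 0) adir <- -adir
  adir <- unitv(adir)
  axis_at <- function(psi, phi) {
    ps <- deg2rad(psi); ph <- deg2rad(phi)
    unitv(cos(ph) * (cos(ps) * r0 + sin(ps) * mdir) + sin(ph) * adir)
  }
  phis <- seq(-config$phi_halfwidth, config$phi_halfwidth,
              by = config$phi_step)
  phi_warm <- 0
  pitch <- 2 * config$min_length / config$n_axial
  feasible_at <- function(psi, phi) {
    cyl <- screw_cylinder(L, axis_at(psi, phi), config$diameter, feas_len)
    contains_cylinder(mesh, cyl, tol = config$tol,
                      entry_normal = entry_normal,
                      entry_band = config$entry_band,
                      n_axial = config$n_axial, n_circ = config$n_circ,
                      n_cap = config$n_cap, align = mdir,
                      axial_pitch = pitch)$contained
  }
  feasible <- function(psi) {
    ord <- order(abs(phis - phi_warm))
    for (phi in phis[ord]) {
      if (feasible_at(psi, phi)) {
        phi_warm <<- phi
        return(TRUE)
      }
    }
    FALSE
  }
  psi_min <- config$psi_range[1]
  psi_max <- config$psi_range[2]
  step <- 3
  # find a feasible medial tilt
  psi_feas <- NA
  for (psi in seq(30, psi_max, by = step)) {
    if (feasible(psi)) { psi_feas <- psi; break }
  }
  if (is.na(psi_feas)) {
    for (psi in seq(30 - step, psi_min, by = -step)) {
      if (feasible(psi)) { psi_feas <- psi; break }
    }
  }
  if (is.na(psi_feas)) {
    stop("no-corridor error: no contained direction from L", call. = FALSE)
  }
  # walk laterally (decreasing psi) to bracket the minimal medial tilt
  psi_infeas <- NA
  psi <- psi_feas - step
  while (psi >= psi_min) {
    if (!feasible(psi)) { psi_infeas <- psi; break }
    psi_feas <- psi
    psi <- psi - step
  }
  capped <- is.na(psi_infeas)
  if (capped) {
    psi_lo <- psi_min
    if (!feasible(psi_lo)) {
      # range end infeasible after all (non-monotone pocket): bisect anyway
      capped <- FALSE
      psi_infeas <- psi_lo
      psi_lo <- psi_feas
    } else {
      psi_feas <- psi_min
    }
  }
  if (!capped) {
    lo <- psi_infeas; hi <- psi_feas
    while (hi - lo > config$ang_tol) {
      mid <- (lo + hi) / 2
      if (feasible(mid)) hi <- mid else lo <- mid
    }
    psi_feas <- hi
    psi_infeas <- lo
  }
  # centre the anterior/posterior tilt inside its feasible interval at the
  # reported medial tilt
  stopifnot(feasible(psi_feas))
  phi_c <- phi_warm
  edge <- function(dir) {
    lo <- phi_c
    hi <- phi_c + dir * (config$phi_halfwidth - phi_c * dir)
    if (feasible_at(psi_feas, hi)) return(hi)
    while (abs(hi - lo) > 0.5) {
      mid <- (lo + hi) / 2
      if (feasible_at(psi_feas, mid)) lo <- mid else hi <- mid
    }
    lo
  }
  phi_star <- (edge(1) + edge(-1)) / 2
  if (!feasible_at(psi_feas, phi_star)) phi_star <- phi_c
  axis <- axis_at(psi_feas, phi_star)
  L0 <- screw_length(mesh, L, axis, config, entry_normal, align = mdir)
  list(screw = screw_cylinder(L, axis, config$diameter, L0), L0 = L0,
       psi_deg = psi_feas, phi_deg = phi_star,
       psi_bracket = c(violated = if (capped) NA_real_ else psi_infeas,
                       contained = psi_feas),
       capped = capped,
       frame = list(r = r0, m = mdir, a = adir))
}

#' Cross-section measuring planes
#'
#' Builds the four measuring planes: plane 1 spanned by the perpendicular
#' from L to the brim and the tangential screw axis; plane 2 orthogonal to
#' plane 1 through the tangential axis; plane 3 spanned by the perpendicular
#' from M to the brim and the direction to O (the inner screw insertion
#' plane); plane 4 orthogonal to plane 3 through O and M.  Reference lines
#' at M and L are the in-plane directions perpendicular to the local
#' cortical tangent, pointing into the bone.
#'
#' @param mesh watertight [surface_mesh()].
#' @param M,L insertion sites; `O` lowest symphysis point.
#' @param brim ordered brim polyline.
#' @param tangential_axis unit axis of the obturator-tangential screw (may
#'   be `NULL`: planes 1/2 are then omitted).
#' @return list of planes `plane1..plane4` (each `point` + unit `normal`),
#'   reference lines `ref_M_plane3`, `ref_M_plane4`, `ref_L_plane1`,
#'   `ref_L_plane2`, `ref_L_plane3par`, perpendiculars `w_M`, `w_L`, and
#'   entry normals `normal_M`, `normal_L`.
#' @export
build_cross_sections <- function(mesh, M, L, O, brim, tangential_axis = NULL) {
  w_M <- unitv(polyline_nearest(brim, M)$point - M)
  w_L <- unitv(polyline_nearest(brim, L)$point - L)
  n_M <- patch_normal(mesh, M)
  n_L <- patch_normal(mesh, L)
  om <- O - M
  if (vnorm(om) < 1) {
    stop("degenerate-landmark error: M and O nearly coincide", call. = FALSE)
  }
  n3v <- cross3(w_M, om)
  if (vnorm(n3v) < 1e-8) {
    stop("geometry error: perpendicular from M is parallel to OM",
         call. = FALSE)
  }
  n3 <- unitv(n3v)
  n4 <- unitv(cross3(n3, om))
  inplane_ref <- function(nrm, plane_n) {
    v <- project_to_plane(-nrm, plane_n)
    if (vnorm(v) < 1e-8) {
      stop("geometry error: cortical normal is orthogonal to the measuring plane",
           call. = FALSE)
    }
    unitv(v)
  }
  out <- list(
    plane3 = list(point = M, normal = n3),
    plane4 = list(point = M, normal = n4),
    ref_M_plane3 = inplane_ref(n_M, n3),
    ref_M_plane4 = inplane_ref(n_M, n4),
    ref_L_plane3par = inplane_ref(n_L, n3),
    w_M = w_M, w_L = w_L, normal_M = n_M, normal_L = n_L)
  if (!is.null(tangential_axis)) {
    a <- unitv(tangential_axis)
    n1v <- cross3(w_L, a)
    if (vnorm(n1v) < 1e-8) {
      stop("geometry error: tangential axis is parallel to the perpendicular from L",
           call. = FALSE)
    }
    n1 <- unitv(n1v)
    n2 <- unitv(cross3(n1, a))
    out$plane1 <- list(point = L, normal = n1)
    out$plane2 <- list(point = L, normal = n2)
    out$ref_L_plane1 <- inplane_ref(n_L, n1)
    out$ref_L_plane2 <- inplane_ref(n_L, n2)
  }
  out
}

#' Signed angle of an axis against a reference line within a plane
#'
#' Projects `axis` into the plane and measures its angle from
#' `reference_line`; the sign follows the component along `positive_dir`.
#'
#' @param axis direction to measure.
#' @param plane_normal unit plane normal.
#' @param reference_line unit in-plane reference.
#' @param positive_dir in-plane direction whose side counts positive.
#' @return signed angle in degrees.
#' @export
measure_angle_in_plane <- function(axis, plane_normal, reference_line,
                                   positive_dir) {
  n <- unitv(plane_normal)
  ap <- project_to_plane(axis, n)
  if (vnorm(ap) < 1e-9) {
    stop("geometry error: axis is orthogonal to the measuring plane",
         call. = FALSE)
  }
  ang <- vangle(ap, reference_line)
  pd <- project_to_plane(positive_dir, n)
  sgn <- sign(sum(ap * pd))
  if (sgn == 0) sgn <- 1
  ang * sgn
}

#' Medial inclination angle of the insertion plane
#'
#' The angle between the OM line and the reference line (the in-plane
#' perpendicular to the cortical tangent at M), both projected into the
#' measuring plane through O and M.
#'
#' @param M inner insertion site; `O` lowest symphysis point.
#' @param reference_line unit reference direction at M.
#' @param plane_normal unit normal of the measuring plane (plane 4).
#' @return angle in degrees, in `[0, 90)`.
#' @export
medial_inclination_angle <- function(M, O, reference_line, plane_normal) {
  if (vnorm(O - M) < 1) {
    stop("degenerate-landmark error: |OM| < 1 mm", call. = FALSE)
  }
  n <- unitv(plane_normal)
  om <- project_to_plane(O - M, n)
  rf <- project_to_plane(reference_line, n)
  if (vnorm(om) < 1e-9 || vnorm(rf) < 1e-9) {
    stop("geometry error: degenerate projection in plane 4", call. = FALSE)
  }
  ang <- vangle(om, rf)
  if (ang >= 90) ang <- 180 - ang
  ang
}

#' Safe-region pattern along the tangential screw axis
#'
#' Projects the anterior and posterior cortical walls (faces seen edge-on
#' along the axis) onto the plane perpendicular to the tangential screw and
#' classifies how their projected boundary lines relate: crossing within the
#' projected bone silhouette with apex angle >= `apex_threshold` is a blunt
#' V, crossing below it a sharp V, and no crossing is the disjoint pattern.
#'
#' @param mesh watertight [surface_mesh()].
#' @param tangential_axis unit axis of the obturator-tangential screw.
#' @param lateral_hint in-plane direction of the lateral coordinate; when
#'   `NULL` the principal direction of the projected edge-on faces is used.
#' @param anterior_hint direction with a positive anterior component (labels
#'   the two boundaries; the pattern itself is label-invariant).
#' @param apex_threshold blunt/sharp separation (deg).
#' @param edge_on_tol faces with `|normal . axis|` below this are edge-on.
#' @param side_tol minimum in-plane anterior/posterior normal component for
#'   a face to join a boundary.
#' @return a `safe_region` list with `pattern` (`"blunt_V"`, `"sharp_V"`,
#'   `"disjoint"`), `apex_angle_deg` (`NA` when disjoint), `crossing_xi`,
#'   `anterior_boundary`, `posterior_boundary` (projected polylines),
#'   `basis`.
#' @export
safe_region <- function(mesh, tangential_axis, lateral_hint = NULL,
                        anterior_hint = NULL, apex_threshold = 90,
                        edge_on_tol = 0.35, side_tol = 0.3) {
  a <- unitv(tangential_axis)
  g <- mesh_geom(mesh)
  nd <- as.vector(g$unit %*% a)
  edge_on <- abs(nd) < edge_on_tol
  if (sum(edge_on) < 4) {
    stop("geometry error: projection yields too few edge-on faces",
         call. = FALSE)
  }
  if (is.null(lateral_hint)) {
    cen <- g$centroids[edge_on, , drop = FALSE]
    cen_p <- cen - outer(as.vector(cen %*% a), a)
    pc <- prcomp(cen_p, center = TRUE, scale. = FALSE)
    lateral_hint <- pc$rotation[, 1]
  }
  e1 <- unitv(project_to_plane(lateral_hint, a))
  e2 <- cross3(a, e1)
  if (!is.null(anterior_hint) && sum(e2 * anterior_hint) < 0) e2 <- -e2
  n2 <- as.vector(g$unit %*% e2)
  ant <- edge_on & n2 > side_tol
  post <- edge_on & n2 < -side_tol
  if (sum(ant) < 2 || sum(post) < 2) {
    stop("geometry error: projection yields fewer than 2 boundary segments",
         call. = FALSE)
  }
  ref <- g$centroids[which(edge_on)[1], ]
  proj <- function(sel) {
    c0 <- g$centroids[sel, , drop = FALSE] -
      matrix(ref, sum(sel), 3, byrow = TRUE)
    cbind(xi = as.vector(c0 %*% e1), eta = as.vector(c0 %*% e2))
  }
  pa <- proj(ant)
  pp <- proj(post)
  v0 <- mesh$vertices - matrix(ref, nrow(mesh$vertices), 3, byrow = TRUE)
  sil_range <- range(as.vector(v0 %*% e1))
  bound_line <- function(pts) {
    rng <- range(pts[, 1])
    nb <- max(2, min(40, round(diff(rng) / 2)))
    brk <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = nb + 1)
    bin <- findInterval(pts[, 1], brk, rightmost.closed = TRUE)
    xi <- tapply(pts[, 1], bin, mean)
    eta <- tapply(pts[, 2], bin, median)
    cbind(xi = as.numeric(xi), eta = as.numeric(eta))
  }
  ba <- bound_line(pa)
  bp <- bound_line(pp)
  if (nrow(ba) < 2 || nrow(bp) < 2) {
    stop("geometry error: boundary has fewer than 2 stations", call. = FALSE)
  }
  # evaluate both boundaries over the full silhouette extent, extrapolating
  # with the end slopes
  grid <- seq(sil_range[1], sil_range[2], length.out = 200)
  eval_bound <- function(b) {
    fit_slope <- function(idx) {
      if (length(idx) < 2) return(0)
      stats::coef(stats::lm(b[idx, 2] ~ b[idx, 1]))[2]
    }
    k <- nrow(b)
    head_idx <- seq_len(max(2, ceiling(k * 0.3)))
    tail_idx <- seq(k - max(2, ceiling(k * 0.3)) + 1, k)
    s_lo <- fit_slope(head_idx)
    s_hi <- fit_slope(tail_idx)
    vapply(grid, function(x) {
      if (x < b[1, 1]) return(b[1, 2] + s_lo * (x - b[1, 1]))
      if (x > b[k, 1]) return(b[k, 2] + s_hi * (x - b[k, 1]))
      stats::approx(b[, 1], b[, 2], xout = x, ties = mean)$y
    }, numeric(1))
  }
  ya <- eval_bound(ba)
  yp <- eval_bound(bp)
  dd <- ya - yp
  sc <- which(diff(sign(dd)) != 0)
  if (length(sc) == 0) {
    return(structure(list(pattern = "disjoint", apex_angle_deg = NA_real_,
                          crossing_xi = NA_real_, anterior_boundary = ba,
                          posterior_boundary = bp,
                          basis = list(e1 = e1, e2 = e2, axis = a)),
                     class = "safe_region"))
  }
  i <- sc[1]
  f <- dd[i] / (dd[i] - dd[i + 1])
  xi_c <- grid[i] + f * (grid[i + 1] - grid[i])
  local_slope <- function(b) {
    idx <- which(abs(grid - xi_c) <= max(5, diff(sil_range) / 10))
    y <- if (identical(b, "a")) ya else yp
    stats::coef(stats::lm(y[idx] ~ grid[idx]))[2]
  }
  sa <- local_slope("a")
  sp <- local_slope("p")
  apex <- vangle(c(1, sa, 0), c(1, sp, 0))
  pattern <- if (apex >= apex_threshold) "blunt_V" else "sharp_V"
  structure(list(pattern = pattern, apex_angle_deg = apex,
                 crossing_xi = xi_c, anterior_boundary = ba,
                 posterior_boundary = bp,
                 basis = list(e1 = e1, e2 = e2, axis = a)),
            class = "safe_region")
}
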