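# Parametric pubis phantoms and virtual cohorts.
#
# The phantom idealises the pubic body + superior ramus as a curved bone
# plate in the x-z plane (x medial->lateral from the symphyseal face, z
# superior->inferior, y anterior-posterior): a superior "neck" of width equal
# to the local cortical thickness profile (thick medially at the symphysis,
# thin laterally over the obturator: the medial-thick/lateral-thin gradient
# of the pubic body), flaring anteriorly and posteriorly below the neck into
# the broad body, with a circular obturator through-hole, a tubercle bump on
# the superior boundary and a flat vertical symphyseal face at x = 0.  The
# superior boundary carries the pelvic brim; screws enter the superior neck
# surface, exactly the configuration of the plate-screw corridor problem.

#' Pubis phantom specification
#'
#' @param ramus_length lateral extent of the superior ramus (mm); the whole
#'   x-z outline scales with it.
#' @param symphysis_height vertical extent of the symphyseal face (mm).
#' @param body_thickness_profile superior-surface (neck) thickness stations
#'   from the symphysis (x = 0) to the 55 mm reference station, linearly
#'   interpolated; default thick medial (13 mm at the symphysis) thinning over the
#'   plate region to 7.6 mm laterally.
#' @param thickness_scale multiplies the neck thickness profile.
#' @param obturator_radius radius of the obturator through-hole (mm); 0
#'   removes the hole.
#' @param tubercle_height height of the tubercle bump on the superior
#'   boundary (mm).
#' @param brim_rise lateral rise of the superior boundary (fraction of the
#'   55 mm reference ramus); the brim climbs toward the iliopubic eminence.
#' @param neck_depth depth of the parallel-walled superior neck (mm).
#' @param flare_anterior,flare_posterior wall opening slopes below the neck
#'   (mm per mm of depth).
#' @param flare_span depth over which the flare accumulates (mm).
#' @param intertubercular_distance distance to the contralateral tubercle
#'   apex (mm); positions the off-mesh contralateral landmark.
#' @param n_u,n_v angular / radial mesh resolution.
#' @param seed echoed into the spec (the generator itself is deterministic).
#' @return a `pubis_phantom_spec` list.
#' @export
pubis_phantom_spec <- function(ramus_length = 55, symphysis_height = 41,
                               body_thickness_profile = c(13, 10.6, 8.3, 7.9, 7.6),
                               thickness_scale = 1, obturator_radius = 12,
                               tubercle_height = 1.2, brim_rise = 0.10,
                               neck_depth = 8, flare_anterior = 2.5,
                               flare_posterior = 0.5, flare_span = 6.4,
                               intertubercular_distance = 60,
                               n_u = 84, n_v = 7, seed = 1) {
  if (ramus_length <= 0 || symphysis_height <= 0 || obturator_radius < 0 ||
      tubercle_height < 0 || thickness_scale <= 0) {
    stop("parameter error: phantom lengths must be positive", call. = FALSE)
  }
  if (thickness_scale * body_thickness_profile[1] < 4) {
    stop("parameter error: body thickness at the symphysis end must be >= 4 mm",
         call. = FALSE)
  }
  structure(list(ramus_length = ramus_length,
                 symphysis_height = symphysis_height,
                 body_thickness_profile = body_thickness_profile,
                 thickness_scale = thickness_scale,
                 obturator_radius = obturator_radius,
                 tubercle_height = tubercle_height, brim_rise = brim_rise,
                 neck_depth = neck_depth, flare_anterior = flare_anterior,
                 flare_posterior = flare_posterior, flare_span = flare_span,
                 intertubercular_distance = intertubercular_distance,
                 n_u = n_u, n_v = n_v, seed = seed),
            class = "pubis_phantom_spec")
}

# Foramen centre: scales with the bone but never medial of the outer screw
# region (the method presumes the plate's outer hole clears the foramen).
pubis_hole_center <- function(spec) {
  x_end <- 8 + spec$ramus_length
  c(max(0.58 * x_end, 31), -0.55 * spec$ramus_length)
}

# neck thickness at absolute station x (55 mm reference gradient)
pubis_thickness_at <- function(spec, x) {
  prof <- spec$body_thickness_profile
  stations <- seq(0, 55, length.out = length(prof))
  spec$thickness_scale *
    stats::approx(stations, prof, xout = pmin(pmax(x, 0), 55), rule = 2)$y
}

# Superior boundary height at station x.  Like the cortical thickness
# gradient, the brim profile over the plate region is a local property of
# the pectineal surface and uses the 55 mm reference geometry rather than
# scaling with the subject's ramus: the plate always sits on the same
# superior-surface shape, so entry normals (and with them the angle
# reference lines) do not vary systematically with bone size.
pubis_ztop_at <- function(spec, x, x_end) {
  spec$brim_rise * 55 * (pmax(x, 0) / 63)^1.6 +
    spec$tubercle_height * exp(-((x - 5.5) / 3)^2)
}

# Anterior/posterior half-widths at distance d_top below the superior
# boundary.  Within `neck_depth` of the superior surface the bone keeps the
# cortical thickness profile (the narrow pectineal neck the plate sits on);
# deeper, the walls step open at a steep slope into the broad pubic body.
# The step corner (lip) is a sharp crease carried exactly by a mesh edge
# ring, so grazing screws that clear it gain clearance abruptly - the
# anatomy that lets a maximally tilted screw run long along the cortex.
# The symphyseal and inferior margins keep the full body thickness.
pubis_halfwidths <- function(spec, x, d_top) {
  ramp_a <- pmin(pmax(d_top - spec$neck_depth, 0), spec$flare_span)
  half0 <- pubis_thickness_at(spec, x) / 2
  list(a = half0 + spec$flare_anterior * ramp_a,
       b = half0 + spec$flare_posterior * ramp_a)
}

# distance from 2D points (n x 2) to the superior boundary polyline
dist_to_polyline_2d <- function(P, poly) {
  n <- nrow(poly)
  ax <- poly[-n, 1]; az <- poly[-n, 2]
  ex <- poly[-1, 1] - ax; ez <- poly[-1, 2] - az
  L2 <- ex^2 + ez^2
  vapply(seq_len(nrow(P)), function(i) {
    tt <- ((P[i, 1] - ax) * ex + (P[i, 2] - az) * ez) / pmax(L2, 1e-18)
    tt <- pmin(pmax(tt, 0), 1)
    sqrt(min((P[i, 1] - (ax + tt * ex))^2 + (P[i, 2] - (az + tt * ez))^2))
  }, numeric(1))
}

# dense tagged outline polyline in the x-z plane (clockwise from the
# top-medial corner)
pubis_outline <- function(spec) {
  x_end <- 8 + spec$ramus_length
  C <- pubis_hole_center(spec)
  ro <- max(spec$obturator_radius, 0.75)
  A <- c(0, pubis_ztop_at(spec, 0, x_end))
  E <- c(x_end, pubis_ztop_at(spec, x_end, x_end))
  D <- c(x_end, min(-0.46 * spec$ramus_length, C[2] - 3))
  B <- c(0, -spec$symphysis_height)
  # inferior boundary: cubic spline through the symphysis base, the deepest
  # point of the inferior ramus (medial, under the screw corridor, scaling
  # with ramus length) and an anchor clearing the foramen from below
  x_dip <- min(max(0.30 * x_end, 14), C[1] - 6)
  z_dip <- min(-1.02 * spec$ramus_length, C[2] - ro - 10, B[2] - 2)
  z_under <- min(C[2] - ro - 10, D[2] - 2)
  kx <- c(0, x_dip, C[1], x_end)
  kz <- c(B[2], z_dip, z_under, D[2])
  sf <- stats::splinefun(kx, kz, method = "natural")
  xs <- seq(0, x_end, length.out = 220)
  top <- cbind(xs, pubis_ztop_at(spec, xs, x_end))
  lat <- cbind(x_end, seq(E[2], D[2], length.out = 24))
  xb <- seq(x_end, 0, length.out = 160)
  bot <- cbind(xb, sf(xb))
  med <- cbind(0, seq(B[2], A[2], length.out = 50))
  pts <- rbind(top, lat[-1, ], bot[-1, ], med[-1, ])
  tags <- c(rep("top", nrow(top)), rep("lateral", nrow(lat) - 1),
            rep("bottom", nrow(bot) - 1), rep("medial", nrow(med) - 1))
  # drop the duplicated closing point
  n <- nrow(pts)
  if (vnorm(c(pts[n, ] - pts[1, ], 0)) < 1e-9) {
    pts <- pts[-n, , drop = FALSE]
    tags <- tags[-n]
  }
  list(points = pts, tags = tags, corners = list(A = A, E = E, D = D, B = B),
       x_end = x_end)
}

# outermost intersection of the ray C + t*dir with the closed outline;
# returns radius and the segment index (vectorised over segments)
ray_outline_hit <- function(outline, C, dir) {
  p <- outline$points
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]
  ez <- b[, 2] - a[, 2]
  det <- -dir[1] * ez + dir[2] * ex
  rx <- a[, 1] - C[1]
  rz <- a[, 2] - C[2]
  tt <- (-rx * ez + rz * ex) / det
  uu <- (dir[1] * rz - dir[2] * rx) / det
  ok <- abs(det) > 1e-14 & tt > 1e-9 & uu >= -1e-9 & uu <= 1 + 1e-9
  if (!any(ok)) {
    stop("generation error: outline is not star-shaped around the hole centre",
         call. = FALSE)
  }
  seg <- which(ok)[which.max(tt[ok])]
  list(radius = tt[seg], segment = seg)
}

#' Generate a pubis phantom
#'
#' Builds the watertight mesh (front/back annulus sheets between the
#' obturator rim and the outline, plus the outer and hole walls) and the full
#' landmark set.  Deterministic for a fixed spec.
#'
#' @param spec a [pubis_phantom_spec()].
#' @return list with `mesh`, `landmarks`, `ground_truth` (phantom parameters
#'   echoed; closed-form corridor fields are not available for this phantom
#'   and are `NA`).
#' @export
generate_pubis_phantom <- function(spec) {
  stopifnot(inherits(spec, "pubis_phantom_spec"))
  ol <- pubis_outline(spec)
  x_end <- ol$x_end
  C <- pubis_hole_center(spec)
  ro <- spec$obturator_radius
  # hole must stay strictly interior
  dmin <- min(vapply(seq_len(nrow(ol$points)), function(i) {
    j <- if (i == nrow(ol$points)) 1 else i + 1
    seg_dist_2d(C, ol$points[i, ], ol$points[j, ])
  }, numeric(1)))
  if (ro > 0 && dmin < ro + 3) {
    stop(sprintf(
      "generation error: obturator hole (r=%.1f) too close to the outline (%.1f mm)",
      ro, dmin), call. = FALSE)
  }
  ro_eff <- if (ro > 0) ro else 0.75  # tiny core replaces a true hole
  # angular stations: uniform plus the exact corner / landmark directions
  ang_of <- function(p) atan2(p[2] - C[2], p[1] - C[1])
  # named stations: outline corners, the tubercle apex/edge, and a fixed
  # ladder of superior-surface stations across the plate region so the mesh
  # nodes under the insertion sites sit at identical positions regardless
  # of subject scale (no size-dependent discretisation drift in the angle
  # searches)
  plate_x <- c(5.5, 8, seq(6, 36, by = 2))
  u_named <- c(ang_of(ol$corners$A), ang_of(ol$corners$E),
               ang_of(ol$corners$D), ang_of(ol$corners$B),
               vapply(plate_x, function(x)
                 ang_of(c(x, pubis_ztop_at(spec, x, x_end))), numeric(1)))
  u_uniform <- seq(-pi, pi, length.out = spec$n_u + 1)[-1]
  gap <- 0.35 * 2 * pi / spec$n_u
  keep <- vapply(u_uniform, function(uu) {
    min(abs(c(uu - u_named, uu - u_named + 2 * pi, uu - u_named - 2 * pi)))
  }, numeric(1)) > gap
  u <- sort(unique(round(c(u_uniform[keep], u_named), 10)))
  nu <- length(u)
  hits <- lapply(u, function(uu) ray_outline_hit(ol, C, c(cos(uu), sin(uu))))
  R_out <- vapply(hits, `[[`, numeric(1), "radius")
  tag_u <- ol$tags[vapply(hits, `[[`, integer(1), "segment")]
  nv <- max(spec$n_v, 4)
  # radial stations hole rim -> outline; where a ray crosses the lip crease
  # (neck_depth below the superior boundary) one station is placed exactly
  # on it so the crease is carried by mesh edges
  top_poly <- ol$points[ol$tags == "top", , drop = FALSE]
  xz <- array(NA_real_, c(nu, nv + 1, 2))
  dtop <- matrix(NA_real_, nu, nv + 1)
  for (j in seq_len(nu)) {
    Rj <- R_out[j]
    dir <- c(cos(u[j]), sin(u[j]))
    d_at <- function(r) {
      dist_to_polyline_2d(matrix(C + r * dir, 1, 2), top_poly)
    }
    rc <- NA_real_
    if (d_at(Rj) < spec$neck_depth && d_at(ro_eff) > spec$neck_depth) {
      lo <- ro_eff; hi <- Rj
      for (it in 1:22) {
        mid <- (lo + hi) / 2
        if (d_at(mid) > spec$neck_depth) lo <- mid else hi <- mid
      }
      rc <- (lo + hi) / 2
    }
    if (!is.finite(rc)) rc <- ro_eff + 0.55 * (Rj - ro_eff)
    rc <- min(max(rc, ro_eff + 0.3 * (Rj - ro_eff)), Rj - 0.5)
    rr <- c(seq(ro_eff, rc, length.out = nv - 1), (rc + Rj) / 2, Rj)
    xz[j, , 1] <- C[1] + rr * cos(u[j])
    xz[j, , 2] <- C[2] + rr * sin(u[j])
    dtop[j, ] <- dist_to_polyline_2d(cbind(xz[j, , 1], xz[j, , 2]), top_poly)
  }
  hw <- pubis_halfwidths(spec, as.vector(xz[, , 1]), as.vector(dtop))
  av <- matrix(hw$a, nu, nv + 1)
  bv <- matrix(hw$b, nu, nv + 1)
  idF <- function(j, i) (i) * nu + j
  idB <- function(j, i) nu * (nv + 1) + (i) * nu + j
  nvert <- 2 * nu * (nv + 1)
  V <- matrix(NA_real_, nvert, 3)
  for (i in 0:nv) {
    for (j in seq_len(nu)) {
      V[idF(j, i), ] <- c(xz[j, i + 1, 1], av[j, i + 1], xz[j, i + 1, 2])
      V[idB(j, i), ] <- c(xz[j, i + 1, 1], -bv[j, i + 1], xz[j, i + 1, 2])
    }
  }
  faces <- vector("list", 4 * nu * nv)
  k <- 0
  nxt <- function(j) if (j == nu) 1L else j + 1L
  for (i in 0:(nv - 1)) {
    for (j in seq_len(nu)) {
      jp <- nxt(j)
      # front sheet (outward +y): clockwise in (x,z)
      faces[[k + 1]] <- c(idF(j, i), idF(j, i + 1), idF(jp, i + 1))
      faces[[k + 2]] <- c(idF(j, i), idF(jp, i + 1), idF(jp, i))
      # back sheet (outward -y): counter-clockwise in (x,z)
      faces[[k + 3]] <- c(idB(j, i), idB(jp, i), idB(jp, i + 1))
      faces[[k + 4]] <- c(idB(j, i), idB(jp, i + 1), idB(j, i + 1))
      k <- k + 4
    }
  }
  wall <- vector("list", 4 * nu)
  k <- 0
  for (j in seq_len(nu)) {
    jp <- nxt(j)
    # outer wall
    wall[[k + 1]] <- c(idF(jp, nv), idF(j, nv), idB(j, nv))
    wall[[k + 2]] <- c(idF(jp, nv), idB(j, nv), idB(jp, nv))
    # hole wall (outward into the hole)
    wall[[k + 3]] <- c(idF(jp, 0), idB(jp, 0), idB(j, 0))
    wall[[k + 4]] <- c(idF(jp, 0), idB(j, 0), idF(j, 0))
    k <- k + 4
  }
  F <- do.call(rbind, c(faces, wall))
  mesh <- surface_mesh(V, F)

  top_j <- which(tag_u == "top")
  ordx <- top_j[order(xz[top_j, nv + 1, 1])]
  # the brim carries the plate: keep it to the plate region (the lateral
  # ramus neck grows too thin to take the 5 mm offset curve)
  brim_max_x <- min(40, x_end - 2)
  sel <- ordx[xz[ordx, nv + 1, 1] >= 1.5 & xz[ordx, nv + 1, 1] <= brim_max_x]
  brim <- V[vapply(sel, idB, numeric(1), i = nv), , drop = FALSE]
  j_m <- top_j[which.min(abs(xz[top_j, nv + 1, 1] - 8))]
  mf <- V[idF(j_m, nv), ]
  mb <- V[idB(j_m, nv), ]
  m_curve <- outer(seq(0, 1, length.out = 5), mf - mb) +
    matrix(mb, 5, 3, byrow = TRUE)
  j_apex <- top_j[which.min(abs(xz[top_j, nv + 1, 1] - 5.5))]
  apex <- (V[idF(j_apex, nv), ] + V[idB(j_apex, nv), ]) / 2
  med_j <- which(abs(xz[, nv + 1, 1]) < 1e-6)
  if (length(med_j) < 2) {
    stop("generation error: symphyseal face not resolved", call. = FALSE)
  }
  j_up <- med_j[which.max(xz[med_j, nv + 1, 2])]
  j_lo <- med_j[which.min(xz[med_j, nv + 1, 2])]
  # symphysis landmarks sit on the wall mid-line y = 0 (always between the
  # anterior and posterior faces) so their separation is the face height
  mid_y <- function(j) {
    c(xz[j, nv + 1, 1], 0, xz[j, nv + 1, 2])
  }
  sy_up <- mid_y(j_up)
  sy_lo <- mid_y(j_lo)
  loop <- V[vapply(c(seq_len(nu), 1L), idF, numeric(1), i = 0), , drop = FALSE]
  lm <- landmark_set(
    brim = brim,
    tubercle_edge_m = m_curve,
    symphysis_lowest_O = sy_lo,
    symphysis_upper = sy_up,
    symphysis_lower = sy_lo,
    obturator_loop = loop,
    tubercle_apex = apex,
    contralateral_tubercle_apex = apex -
      c(spec$intertubercular_distance, 0, 0))
  gt <- list(MAIA = NA_real_, MPIA = NA_real_, MIA = NA_real_,
             max_screw_length = NA_real_,
             symphysis_height = spec$symphysis_height,
             intertubercular_distance = spec$intertubercular_distance,
             hole_center = c(C[1], 0, C[2]), hole_radius = ro,
             x_end = x_end, spec = spec,
             n_vertices = nrow(mesh$vertices), n_faces = nrow(mesh$faces))
  list(mesh = mesh, landmarks = lm, ground_truth = gt)
}

# distance from 2D point to segment ab
seg_dist_2d <- function(p, a, b) {
  e <- b - a
  L2 <- sum(e * e)
  t <- if (L2 < 1e-18) 0 else max(0, min(1, sum((p - a) * e) / L2))
  sqrt(sum((p - (a + t * e))^2))
}

# faces of the obturator hole wall (for tangency certificates): faces whose
# centroid is within tol of the hole cylinder surface
obturator_wall_faces <- function(mesh, loop, tol = 1.0) {
  loop <- as_point_matrix(loop)
  C <- colMeans(loop[-nrow(loop), , drop = FALSE])
  ro <- mean(sqrt((loop[, 1] - C[1])^2 + (loop[, 3] - C[3])^2))
  cen <- mesh_geom(mesh)$centroids
  rr <- sqrt((cen[, 1] - C[1])^2 + (cen[, 3] - C[3])^2)
  which(abs(rr - ro) < tol)
}

#' Extrude a 2D polygon into a closed prism mesh
#'
#' @param poly counter-clockwise polygon, n x 2 (x, y).
#' @param z0,z1 extrusion interval (`z0 < z1`).
#' @return a [surface_mesh()].
#' @export
extrude_polygon_mesh <- function(poly, z0, z1) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  Vb <- cbind(poly, z0)
  Vt <- cbind(poly, z1)
  V <- rbind(Vb, Vt)
  fan <- function(offset, rev = FALSE) {
    idx <- lapply(2:(n - 1), function(i) {
      tri <- c(1, i, i + 1) + offset
      if (rev) tri[c(1, 3, 2)] else tri
    })
    do.call(rbind, idx)
  }
  top <- fan(n, rev = FALSE)     # +z cap, CCW
  bottom <- fan(0, rev = TRUE)   # -z cap
  side <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    rbind(c(i, j, n + j), c(i, n + j, n + i))
  }))
  surface_mesh(V, rbind(top, bottom, side))
}

#' Wedge phantoms with a known apex angle
#'
#' Prisms whose cross-section perpendicular to the extrusion axis is either
#' a triangle with the stated apex angle (converging anterior/posterior
#' walls) or a rectangle (parallel walls); the ground-truth classification
#' of [safe_region()] along the extrusion axis is therefore known exactly.
#'
#' @param apex_angle_deg apex angle (deg), or `NA` for parallel walls.
#' @param depth cross-section extent away from the apex (mm).
#' @param half_gap half wall separation of the parallel variant (mm).
#' @param length extrusion length (mm).
#' @return list with `mesh`, `axis` (extrusion direction), `apex_angle_deg`.
#' @export
generate_wedge_phantom <- function(apex_angle_deg = 120, depth = 40,
                                   half_gap = 8, length = 50) {
  if (is.na(apex_angle_deg)) {
    poly <- rbind(c(0, -half_gap), c(depth, -half_gap),
                  c(depth, half_gap), c(0, half_gap))
  } else {
    h <- depth * tan(deg2rad(apex_angle_deg / 2))
    poly <- rbind(c(0, 0), c(depth, -h), c(depth, h))
  }
  mesh <- extrude_polygon_mesh(poly, -length, 0)
  list(mesh = mesh, axis = c(0, 0, -1), apex_angle_deg = apex_angle_deg)
}

#' Closed tube mesh (regular prism) for containment tests
#'
#' @param radius circumradius (mm); `length` extrusion (mm); `n` polygon
#'   vertex count.
#' @return a [surface_mesh()] of the closed tube around the +z axis from 0 to
#'   `length`.
#' @export
tube_mesh <- function(radius = 5, length = 40, n = 60) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  extrude_polygon_mesh(cbind(radius * cos(ang), radius * sin(ang)), 0, length)
}

#' Virtual cohort specification
#'
#' Per-sex normal distributions of the phantom parameters.  The defaults
#' place the intertubercular distance at 58.40 +/- 6.03 mm (male) and
#' 61.98 +/- 9.04 mm (female) and the symphysis vertical extent at
#' 41.82 +/- 4.65 mm (male) and 39.85 +/- 3.26 mm (female); ramus length is
#' given the male/female means 55/48 mm with the outer-screw-length spread,
#' and the thickness scale is sex-independent.
#'
#' @param n_male,n_female subjects per group.
#' @param seed integer; per-subject substreams use `seed + subject index`.
#' @param distributions data frame with columns `parameter`, `mean_male`,
#'   `sd_male`, `mean_female`, `sd_female`.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_male = 40, n_female = 40, seed = 1,
                        distributions = cohort_default_distributions()) {
  if (n_male < 1 || n_female < 1) {
    stop("parameter error: need at least one subject per group", call. = FALSE)
  }
  if (any(distributions$sd_male <= 0) || any(distributions$sd_female <= 0)) {
    stop("parameter error: distribution sds must be positive", call. = FALSE)
  }
  structure(list(n_male = n_male, n_female = n_female, seed = seed,
                 distributions = distributions), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
cohort_default_distributions <- function() {
  data.frame(
    parameter = c("intertubercular_distance", "symphysis_height",
                  "ramus_length", "thickness_scale"),
    mean_male = c(58.40, 41.82, 55, 1),
    sd_male = c(6.03, 4.65, 6.36, 0.04),
    mean_female = c(61.98, 39.85, 48, 1),
    sd_female = c(9.04, 3.26, 8.65, 0.04),
    stringsAsFactors = FALSE)
}

#' Sample a virtual cohort
#'
#' Draws per-subject phantom parameters independently from the per-sex
#' normals (with wide physiological clamps protecting mesh generation) and
#' returns one phantom spec per subject plus a manifest.
#'
#' @param spec a [cohort_spec()].
#' @param n_u,n_v mesh resolution forwarded to the phantom specs.
#' @return list with `subjects` (list of `id`, `sex`, `spec`) and `manifest`
#'   (data frame).
#' @export
sample_cohort <- function(spec, n_u = 84, n_v = 7) {
  stopifnot(inherits(spec, "cohort_spec"))
  dist <- spec$distributions
  row_of <- function(p) dist[dist$parameter == p, ]
  draw <- function(p, sex) {
    r <- row_of(p)
    if (sex == "male") rnorm(1, r$mean_male, r$sd_male)
    else rnorm(1, r$mean_female, r$sd_female)
  }
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  sexes <- c(rep("male", spec$n_male), rep("female", spec$n_female))
  subjects <- vector("list", length(sexes))
  rows <- vector("list", length(sexes))
  for (i in seq_along(sexes)) {
    set.seed(spec$seed + i)
    it <- draw("intertubercular_distance", sexes[i])
    sy <- clamp(draw("symphysis_height", sexes[i]), 26, 58)
    ra <- clamp(draw("ramus_length", sexes[i]), 36, 78)
    ts <- clamp(draw("thickness_scale", sexes[i]), 0.85, 1.15)
    ps <- pubis_phantom_spec(ramus_length = ra, symphysis_height = sy,
                             thickness_scale = ts,
                             obturator_radius = 12 * ra / 55,
                             intertubercular_distance = it,
                             n_u = n_u, n_v = n_v, seed = spec$seed + i)
    id <- sprintf("%s%03d", substr(sexes[i], 1, 1), i)
    subjects[[i]] <- list(id = id, sex = sexes[i], spec = ps)
    rows[[i]] <- data.frame(subject_id = id, sex = sexes[i],
                            intertubercular_distance = it,
                            symphysis_height = sy, ramus_length = ra,
                            thickness_scale = ts,
                            obturator_radius = 12 * ra / 55,
                            seed = spec$seed + i,
                            stringsAsFactors = FALSE)
  }
  list(subjects = subjects, manifest = do.call(rbind, rows))
}
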