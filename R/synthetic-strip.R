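# Strip phantoms: closed rectangular slabs with planar anterior/posterior
# cortices an exact distance T apart.  They admit a 2D closed-form (and an
# independent dense-sweep) solution for the maximal tilt of a screw entering
# the top face, which anchors the acceptance tests of the 3D containment
# searches.
#
# Phantom frame: x in [0, W] medial->lateral, y in [0, T] with the anterior
# cortex at y = 0 and the posterior cortex at y = T, z in [-H, 0] with the
# entry (top) face at z = 0.

#' Strip phantom specification
#'
#' @param thickness_T anterior-posterior cortical wall separation (mm).
#' @param height_H slab depth below the entry face (mm).
#' @param width_W medial-lateral extent (mm).
#' @param entry_offset_da entry distance from the anterior wall (mm).
#' @param entry_offset_dl entry distance from the medial end (mm).
#' @return a `strip_phantom_spec` list.
#' @export
strip_phantom_spec <- function(thickness_T = 20, height_H = 60, width_W = 40,
                               entry_offset_da = 10, entry_offset_dl = 20) {
  if (thickness_T <= 3.5) {
    stop("parameter error: thickness_T must exceed the 3.5 mm screw",
         call. = FALSE)
  }
  if (entry_offset_da <= 0 || entry_offset_da >= thickness_T) {
    stop("parameter error: entry_offset_da must lie strictly inside (0, T)",
         call. = FALSE)
  }
  if (height_H <= 0 || width_W <= 0) {
    stop("parameter error: height_H and width_W must be positive",
         call. = FALSE)
  }
  structure(list(thickness_T = thickness_T, height_H = height_H,
                 width_W = width_W, entry_offset_da = entry_offset_da,
                 entry_offset_dl = entry_offset_dl),
            class = "strip_phantom_spec")
}

# closed axis-aligned box mesh [0,W]x[0,T]x[-H,0]
box_mesh <- function(W, T, H) {
  v <- rbind(c(0, 0, -H), c(W, 0, -H), c(W, T, -H), c(0, T, -H),
             c(0, 0, 0), c(W, 0, 0), c(W, T, 0), c(0, T, 0))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),       # bottom  (z = -H)
             c(5, 6, 7), c(5, 7, 8),       # top     (z = 0)
             c(1, 2, 6), c(1, 6, 5),       # anterior (y = 0)
             c(4, 8, 7), c(4, 7, 3),       # posterior (y = T)
             c(1, 5, 8), c(1, 8, 4),       # medial  (x = 0)
             c(2, 3, 7), c(2, 7, 6))       # lateral (x = W)
  surface_mesh(v, f)
}

#' Generate a strip phantom
#'
#' Builds the slab mesh, a landmark set (brim along the posterior top edge,
#' tubercle-edge curve across the top face at the entry station, symphysis
#' landmarks on the medial face, a vestigial obturator loop on the anterior
#' face, and the entry point) and the analytic ground truth from
#' [strip_phantom_oracle()].
#'
#' @param spec a [strip_phantom_spec()].
#' @param screw_radius screw radius used for the ground truth (mm).
#' @param fixed_length screw length for the fixed-length tilt policy (mm).
#' @param entry_band entry-plane exemption band of the containment test (mm).
#' @return list with `mesh`, `landmarks`, `ground_truth`.
#' @export
generate_strip_phantom <- function(spec, screw_radius = 1.75,
                                   fixed_length = 14, entry_band = 0.5) {
  stopifnot(inherits(spec, "strip_phantom_spec"))
  T <- spec$thickness_T; H <- spec$height_H; W <- spec$width_W
  da <- spec$entry_offset_da; dl <- spec$entry_offset_dl
  mesh <- box_mesh(W, T, H)
  # brim inset from the lateral faces so its tangent frame is unambiguous
  xs <- seq(min(0.75, W / 4), W - min(0.75, W / 4),
            length.out = max(9, ceiling(W / 2) + 1))
  brim <- cbind(xs, T, 0)
  m_curve <- cbind(dl, seq(T, max(T - 10, 0), length.out = 6), 0)
  loop_t <- seq(0, 2 * pi, length.out = 17)
  loop <- cbind(W / 2 + cos(loop_t), 0, -H / 2 + sin(loop_t))
  loop[17, ] <- loop[1, ]
  lm <- landmark_set(
    brim = brim,
    tubercle_edge_m = m_curve,
    symphysis_lowest_O = c(0, T / 2, -H),
    symphysis_upper = c(0, T / 2, 0),
    symphysis_lower = c(0, T / 2, -H),
    obturator_loop = loop,
    tubercle_apex = c(dl, T, 0),
    entry = c(dl, da, 0))
  gt <- strip_phantom_oracle(T = T, da = da, r = screw_radius,
                             length_policy = "fixed-14",
                             fixed_length = fixed_length,
                             entry_band = entry_band, H = H)
  gt$n_vertices <- nrow(mesh$vertices)
  gt$n_faces <- nrow(mesh$faces)
  list(mesh = mesh, landmarks = lm, ground_truth = gt)
}

# First theta (deg) at which the 2D wall constraint binds.  The binding
# vertex of the band-clipped screw rectangle reaches the wall when
# L sin(theta) + r cos(theta) = clearance; beyond clearance
# sqrt(L^2 + r^2 - band^2) the far corner leaves the tested band before it
# can touch the wall and no tilt in [0, cap] binds.
strip_max_tilt_closed_form <- function(clearance, r, L, band = 0.5, cap = 89,
                                       tol = 0.05) {
  R <- sqrt(L^2 + r^2)
  clearance <- clearance + tol  # the containment test tolerates tol outside
  if (clearance < r) {
    stop("no-corridor error: entry closer to the wall than the screw radius",
         call. = FALSE)
  }
  if (clearance >= sqrt(R^2 - band^2)) return(cap)
  th <- asin(clearance / R) - atan2(r, L)
  max(0, min(cap, rad2deg(th)))
}

# 2D rectangle-in-strip feasibility used by the dense sweep: the screw
# rectangle is clipped to the tested half-plane z <= -band and every clipped
# vertex must satisfy 0 <= y <= T (and z >= -H).  Independent of the closed
# form above.
strip_rect_feasible <- function(T, da, r, L, theta_deg, band, H = Inf,
                                tol = 0.05) {
  th <- deg2rad(theta_deg)
  d <- c(-sin(th), -cos(th))      # axis: (y, z), anterior tilt lowers y
  p <- c(-cos(th), sin(th))       # lateral offset direction
  corners <- rbind(
    c(da, 0) + 0 * d + r * p,
    c(da, 0) + 0 * d - r * p,
    c(da, 0) + L * d - r * p,
    c(da, 0) + L * d + r * p)
  poly <- clip_halfplane(corners, normal = c(0, -1), offset = band)
  if (nrow(poly) == 0) return(FALSE)  # never enters the tested bone
  all(poly[, 1] >= -tol - 1e-9 & poly[, 1] <= T + tol + 1e-9 &
        poly[, 2] >= -H - tol - 1e-9)
}

# Sutherland-Hodgman clip of a convex 2D polygon to normal . x >= offset
clip_halfplane <- function(poly, normal, offset) {
  n <- nrow(poly)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1 else i + 1, ]
    da_ <- sum(a * normal) - offset
    db_ <- sum(b * normal) - offset
    if (da_ >= 0) out <- rbind(out, a)
    if ((da_ > 0 && db_ < 0) || (da_ < 0 && db_ > 0)) {
      t <- da_ / (da_ - db_)
      out <- rbind(out, a + t * (b - a))
    }
  }
  out
}

#' Analytic ground truth for a strip phantom
#'
#' Maximal anterior and posterior tilt of a screw entering the top face of a
#' strip of thickness `T` at distance `da` from the anterior wall, plus the
#' maximal tangent screw length along the reference (untilted) direction.
#' The closed form solves the first binding contact of the screw rectangle
#' with a wall; `method = "sweep"` recomputes it by a dense angle sweep with
#' an exact 2D rectangle-in-strip containment test and is the reference
#' oracle.
#'
#' @param T wall separation (mm); `da` entry distance from the anterior wall;
#'   `r` screw radius (mm).
#' @param length_policy `"fixed-14"` (posterior convention) or
#'   `"max-tangent"` (anterior convention; the tilt limit is reached when the
#'   maximal tangent length falls to the 14 mm minimum, so the limiting angle
#'   coincides with the fixed-14 answer and the tangent length at that angle
#'   is reported).
#' @param fixed_length minimum implantable screw length (mm).
#' @param entry_band entry-plane exemption band (mm), shared with the 3D
#'   containment test.
#' @param H slab depth (mm); `Inf` for the pure two-wall problem.
#' @param method `"closed-form"` or `"sweep"`.
#' @param sweep_step sweep resolution in degrees.
#' @param cap largest tilt considered (deg).
#' @return list with `anterior_max_deg`, `posterior_max_deg`,
#'   `max_length_reference`, `anterior_tangent_length`, and the inputs.
#' @export
strip_phantom_oracle <- function(T, da, r = 1.75,
                                 length_policy = c("fixed-14", "max-tangent"),
                                 fixed_length = 14, entry_band = 0.5,
                                 H = Inf, method = c("closed-form", "sweep"),
                                 sweep_step = 0.01, cap = 89, tol = 0.05) {
  length_policy <- match.arg(length_policy)
  method <- match.arg(method)
  if (2 * r >= T) {
    stop("no-corridor error: screw diameter exceeds wall separation",
         call. = FALSE)
  }
  if (da < r - 1e-12 || da > T - r + 1e-12) {
    stop("no-corridor error: entry point does not admit the screw",
         call. = FALSE)
  }
  L <- fixed_length
  if (method == "closed-form") {
    ant <- strip_max_tilt_closed_form(da, r, L, band = entry_band, cap = cap,
                                      tol = tol)
    post <- strip_max_tilt_closed_form(T - da, r, L, band = entry_band,
                                       cap = cap, tol = tol)
  } else {
    sweep_max <- function(clearance) {
      thetas <- seq(0, cap, by = sweep_step)
      for (i in seq_along(thetas)) {
        if (!strip_rect_feasible(T, clearance, r, L, thetas[i],
                                 band = entry_band, H = H, tol = tol)) {
          return(if (i == 1) 0 else thetas[i - 1])
        }
      }
      cap
    }
    ant <- sweep_max(da)
    post <- sweep_max(T - da)
  }
  max_len_ref <- if (is.finite(H)) H else NA_real_
  # tangent length at the maximal anterior tilt: first wall or bottom exit
  th <- deg2rad(ant)
  ant_len <- if (ant >= cap - 1e-9 || sin(th) < 1e-9) {
    max_len_ref
  } else {
    len_wall <- (da + tol - r * cos(th)) / sin(th)
    len_bot <- if (is.finite(H)) (H + tol - r * sin(th)) / cos(th) else Inf
    min(len_wall, len_bot)
  }
  list(anterior_max_deg = ant, posterior_max_deg = post,
       max_length_reference = max_len_ref,
       anterior_tangent_length = ant_len,
       T = T, da = da, r = r, length_policy = length_policy,
       fixed_length = fixed_length, entry_band = entry_band, H = H,
       method = method, tol = tol)
}

# maximal tangent length of a screw tilted theta (deg, anterior positive)
# inside the strip; 2D chord oracle used by the screw-length tests
strip_tangent_length <- function(T, da, r, theta_deg, H, tol = 0.05) {
  th <- deg2rad(abs(theta_deg))
  clearance <- tol + if (theta_deg >= 0) da else T - da
  len_bot <- (H + tol - r * sin(th)) / cos(th)
  if (sin(th) < 1e-12) return(len_bot)
  len_wall <- (clearance - r * cos(th)) / sin(th)
  min(len_wall, len_bot)
}
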