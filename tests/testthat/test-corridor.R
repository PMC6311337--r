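# The containment core against analytic fixtures.

test_that("coaxial cylinder in a closed tube reports the analytic clearance", {
  tb <- mesh_with_accel(tube_mesh(5, 40, 60))
  thin <- contains_cylinder(tb, screw_cylinder(c(0, 0, 10), c(0, 0, 1), 2, 20),
                            details = TRUE)
  expect_true(thin$contained)
  # polygonal tube inradius 5 cos(pi/60); lateral clearance ~ 4
  expect_equal(thin$clearance, 5 * cos(pi / 60) - 1, tolerance = 0.02)
  fat <- contains_cylinder(tb, screw_cylinder(c(0, 0, 10), c(0, 0, 1), 12, 20),
                           details = TRUE)
  expect_false(fat$contained)
  expect_lt(fat$clearance, -0.9)
})

test_that("non-watertight meshes are refused", {
  tb <- tube_mesh(5, 40, 24)
  holed <- surface_mesh(tb$vertices, tb$faces[-1, ], orient = FALSE)
  expect_error(
    contains_cylinder(holed, screw_cylinder(c(0, 0, 10), c(0, 0, 1), 2, 10)),
    "watertight")
})

test_that("strip tilts one tolerance below the oracle fit, one above break", {
  spec <- strip_phantom_spec(20, 60, 40, 10, 20)
  ph <- generate_strip_phantom(spec)
  mesh <- mesh_with_accel(ph$mesh)
  entry <- ph$landmarks$entry
  o <- strip_phantom_oracle(20, 10, 1.75, method = "sweep")
  nrm <- c(0, 0, 1)
  tilt_cyl <- function(theta) {
    th <- theta * pi / 180
    screw_cylinder(entry, c(0, -sin(th), -cos(th)), 3.5, 14)
  }
  below <- contains_cylinder(mesh, tilt_cyl(o$anterior_max_deg - 1),
                             entry_normal = nrm, align = c(0, -1, 0))
  above <- contains_cylinder(mesh, tilt_cyl(o$anterior_max_deg + 1),
                             entry_normal = nrm, align = c(0, -1, 0))
  expect_true(below$contained)
  expect_false(above$contained)
})

test_that("bisection matches the dense-sweep oracle across the strip grid", {
  cfg <- corridor_config()
  for (T in c(8, 12, 20, 30)) {
    das <- seq(1.75, T - 1.75, length.out = 5)
    for (da in das) {
      os <- strip_phantom_oracle(T, da, 1.75, method = "sweep",
                                 sweep_step = 0.02)
      ph <- generate_strip_phantom(strip_phantom_spec(T, 60, 40, da, 20))
      mesh <- mesh_with_accel(ph$mesh)
      e <- ph$landmarks$entry
      ra <- max_inclination_angle(mesh, e, c(1, 0, 0), c(0, 0, -1),
                                  "anterior", c(0, -1, 0), "fixed-14", cfg,
                                  entry_normal = c(0, 0, 1))
      rp <- max_inclination_angle(mesh, e, c(1, 0, 0), c(0, 0, -1),
                                  "posterior", c(0, -1, 0), "fixed-14", cfg,
                                  entry_normal = c(0, 0, 1))
      expect_lt(abs(ra$angle_deg - os$anterior_max_deg), 0.1)
      expect_lt(abs(-rp$angle_deg - os$posterior_max_deg), 0.1)
      expect_gte(ra$angle_deg, 0)
      expect_lte(rp$angle_deg, 0)
    }
  }
})

test_that("screw lengths match the 2D chord oracle", {
  cfg <- corridor_config()
  ph <- generate_strip_phantom(strip_phantom_spec(20, 60, 40, 10, 20))
  mesh <- mesh_with_accel(ph$mesh)
  e <- ph$landmarks$entry
  # straight down: full depth
  l0 <- screw_length(mesh, e, c(0, 0, -1), cfg)
  expect_lt(abs(l0 - 60), 0.1)
  # tilted: anterior wall chord
  for (th in c(10, 20, 30)) {
    ax <- c(0, -sin(th * pi / 180), -cos(th * pi / 180))
    lo <- pubicorridor:::strip_tangent_length(20, 10, 1.75, th, 60)
    lm_ <- screw_length(mesh, e, ax, cfg, align = c(0, -1, 0))
    expect_lt(abs(lm_ - lo), 0.1)
  }
  # axis pointing straight out of the bone: below minimum
  expect_error(screw_length(mesh, e, c(0, 0, 1), cfg), "below-minimum")
})

test_that("posterior maximum grows with wall separation (oracle monotone)", {
  cfg <- corridor_config()
  angs <- vapply(c(12, 20, 30), function(T) {
    ph <- generate_strip_phantom(strip_phantom_spec(T, 60, 40, 6, 20))
    mesh <- mesh_with_accel(ph$mesh)
    abs(max_inclination_angle(mesh, ph$landmarks$entry, c(1, 0, 0),
                              c(0, 0, -1), "posterior", c(0, -1, 0),
                              "fixed-14", cfg)$angle_deg)
  }, numeric(1))
  expect_true(all(diff(angs) > 0))
})

test_that("cross-section planes satisfy their orthogonality contracts", {
  res <- default_pubis_result()
  cs <- res$planes
  expect_lt(abs(sum(cs$plane1$normal * cs$plane2$normal)), 1e-6)
  expect_lt(abs(sum(cs$plane3$normal * cs$plane4$normal)), 1e-6)
  # plane 3 contains M and O
  M <- res$insertion$M
  O <- res$landmarks$symphysis_lowest_O
  expect_lt(abs(sum((O - M) * cs$plane3$normal)), 1e-6)
  # plane 2 contains the tangential axis
  expect_lt(abs(sum(res$tangential$screw$axis * cs$plane2$normal)), 1e-6)
  # reference lines are unit and in-plane
  expect_equal(sqrt(sum(cs$ref_M_plane3^2)), 1, tolerance = 1e-9)
  expect_lt(abs(sum(cs$ref_M_plane3 * cs$plane3$normal)), 1e-9)
})

test_that("cross sections on a strip match hand-computed planes", {
  ph <- generate_strip_phantom(strip_phantom_spec(20, 60, 40, 10, 20))
  mesh <- mesh_with_accel(ph$mesh)
  lm <- ph$landmarks
  M <- c(20, 15, 0); L <- c(30, 15, 0)
  O <- lm$symphysis_lowest_O  # (0, 10, -60)
  cs <- build_cross_sections(mesh, M, L, O, lm$brim,
                             tangential_axis = c(0, 0, -1))
  # w_L is +y (toward the brim at y = 20); plane1 = span(y, z) -> normal x
  expect_equal(abs(cs$plane1$normal), c(1, 0, 0), tolerance = 1e-6)
  expect_equal(abs(cs$plane2$normal), c(0, 1, 0), tolerance = 1e-6)
  n3 <- pubicorridor:::unitv(pubicorridor:::cross3(c(0, 1, 0), O - M))
  expect_lt(min(sqrt(sum((cs$plane3$normal - n3)^2)),
                sqrt(sum((cs$plane3$normal + n3)^2))), 1e-6)
})

test_that("medial inclination angle reproduces constructed angles", {
  M <- c(10, 0, 0)
  ref <- c(0, 0, -1)
  n4 <- c(0, 1, 0)
  expect_equal(medial_inclination_angle(M, M + 5 * ref, ref, n4), 0,
               tolerance = 1e-9)
  O45 <- M + 5 * c(-sin(pi / 4), 0, -cos(pi / 4))
  expect_equal(medial_inclination_angle(M, O45, ref, n4), 45,
               tolerance = 1e-9)
  expect_error(medial_inclination_angle(M, M + c(0.1, 0, 0), ref, n4),
               "degenerate-landmark")
  # independent trigonometric check on the pubis phantom
  res <- default_pubis_result()
  cs <- res$planes
  M <- res$insertion$M
  O <- res$landmarks$symphysis_lowest_O
  n <- cs$plane4$normal
  pr <- function(v) v - sum(v * n) * n
  a <- pr(O - M); b <- pr(cs$ref_M_plane4)
  ang <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  if (ang >= 90) ang <- 180 - ang
  expect_equal(res$inner$plane_MIA, ang, tolerance = 1e-6)
})

test_that("tangential screw is tangent to the obturator-side cortex", {
  ph <- default_pubis()
  res <- default_pubis_result()
  mesh <- mesh_with_accel(ph$mesh)
  tng <- res$tangential
  wall <- pubicorridor:::obturator_wall_faces(mesh, res$landmarks$obturator_loop)
  pts <- pubicorridor:::cylinder_samples(tng$screw, 64, 16, 16)
  d <- pubicorridor:::cpp_min_dist_to_faces(pubicorridor:::mesh_accel(mesh),
                                            pts, as.integer(wall))
  expect_lt(d, 0.1)
  expect_false(tng$capped)
})

test_that("without an obturator foramen the lateral limit is the outer cortex", {
  ph0 <- generate_pubis_phantom(pubis_phantom_spec(obturator_radius = 0))
  res0 <- analyze_hemipelvis(ph0$mesh, ph0$landmarks,
                             corridor_config(measures = "tangential"))
  res <- default_pubis_result()
  expect_lt(res0$tangential$MIA, res$tangential$MIA)
})

test_that("wedge phantoms classify by their built apex angles", {
  for (case in list(list(120, "blunt_V"), list(40, "sharp_V"),
                    list(NA, "disjoint"))) {
    w <- generate_wedge_phantom(case[[1]])
    sr <- safe_region(w$mesh, w$axis, lateral_hint = c(1, 0, 0),
                      anterior_hint = c(0, 1, 0))
    expect_equal(sr$pattern, case[[2]])
    if (!is.na(case[[1]])) {
      expect_equal(sr$apex_angle_deg, case[[1]], tolerance = 0.02)
    }
  }
})
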