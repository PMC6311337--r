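test_that("planar offset reduces to an exact 5 mm translation", {
  ph <- generate_strip_phantom(strip_phantom_spec(20, 60, 40, 10, 20))
  mesh <- mesh_with_accel(ph$mesh)
  brim <- ph$landmarks$brim
  oc <- offset_brim_curve(mesh, brim, 5,
                          side_hint = ph$landmarks$tubercle_edge_m[3, ])
  expect_equal(oc[, 1], brim[, 1], tolerance = 1e-6)
  expect_equal(oc[, 2], brim[, 2] - 5, tolerance = 1e-6)
  expect_equal(oc[, 3], brim[, 3], tolerance = 1e-6)
  # offset 0 is the identity
  expect_equal(offset_brim_curve(mesh, brim, 0), brim)
})

test_that("offset larger than the wall width falls off and errors", {
  ph <- generate_strip_phantom(strip_phantom_spec(6, 40, 30, 3, 15))
  mesh <- mesh_with_accel(ph$mesh)
  expect_error(
    offset_brim_curve(mesh, ph$landmarks$brim, 12,
                      side_hint = ph$landmarks$tubercle_edge_m[3, ]),
    "geometry error")
})

test_that("pubis offset curve stays 5 mm from the brim (geodesic)", {
  ph <- default_pubis()
  mesh <- mesh_with_accel(ph$mesh)
  lm <- snap_landmarks(ph$landmarks, mesh)
  oc <- offset_brim_curve(mesh, lm$brim, 5,
                          side_hint = lm$tubercle_edge_m[3, ])
  # on the gently curved superior neck the straight-line distance equals the
  # geodesic offset to well under the stated 0.2 mm
  d <- sqrt(rowSums((oc - lm$brim)^2))
  expect_lt(max(abs(d - 5)), 0.2)
  # and on the surface
  dsurf <- sqrt(rowSums((oc - closest_on_mesh(mesh, oc)$points)^2))
  expect_lt(max(dsurf), 1e-6)
})

test_that("insertion points sit at the plate arc distances from S", {
  ph <- default_pubis()
  mesh <- mesh_with_accel(ph$mesh)
  lm <- snap_landmarks(ph$landmarks, mesh)
  oc <- offset_brim_curve(mesh, lm$brim, 5,
                          side_hint = lm$tubercle_edge_m[3, ])
  ip <- locate_insertion_points(mesh, oc, lm$tubercle_edge_m, plate_spec(),
                                O = lm$symphysis_lowest_O)
  # independent arc-length check on a 0.01 mm resampling
  fine <- pubicorridor:::polyline_resample(ip$offset_curve, 0.01)
  s <- pubicorridor:::polyline_arclength(fine)
  arc_of <- function(p) {
    i <- which.min(sqrt(rowSums((fine - matrix(p, nrow(fine), 3,
                                               byrow = TRUE))^2)))
    s[i]
  }
  expect_lt(abs((arc_of(ip$M) - arc_of(ip$S)) - 6.5), 0.1)
  expect_lt(abs((arc_of(ip$L) - arc_of(ip$S)) - 19.5), 0.1)
})

test_that("first_hole_offset 0 puts M at S; short curves error", {
  ph <- generate_strip_phantom(strip_phantom_spec(20, 60, 40, 10, 0.5))
  mesh <- mesh_with_accel(ph$mesh)
  lm <- ph$landmarks
  oc <- offset_brim_curve(mesh, lm$brim, 5, side_hint = lm$tubercle_edge_m[3, ])
  plate0 <- plate_spec(first_hole_offset = 1e-9)
  ip <- locate_insertion_points(mesh, oc, lm$tubercle_edge_m, plate0,
                                O = lm$symphysis_lowest_O)
  expect_lt(sqrt(sum((ip$S - ip$M)^2)), 1e-3)
  # m curve far from the offset curve
  far_m <- lm$tubercle_edge_m
  far_m[, 3] <- far_m[, 3] - 30
  expect_error(locate_insertion_points(mesh, oc, far_m, plate_spec(),
                                       O = lm$symphysis_lowest_O),
               "no-intersection")
  # curve too short beyond S
  long_plate <- plate_spec(hole_pitch = 100)
  expect_error(locate_insertion_points(mesh, oc, lm$tubercle_edge_m,
                                       long_plate, O = lm$symphysis_lowest_O),
               "curve-too-short")
})

test_that("S, M, L are rigid-motion equivariant", {
  ph <- default_pubis()
  place <- function(p) {
    mesh <- mesh_with_accel(p$mesh)
    lm <- snap_landmarks(p$landmarks, mesh)
    oc <- offset_brim_curve(mesh, lm$brim, 5,
                            side_hint = lm$tubercle_edge_m[3, ])
    locate_insertion_points(mesh, oc, lm$tubercle_edge_m, plate_spec(),
                            O = lm$symphysis_lowest_O)
  }
  ip1 <- place(ph)
  R <- rotation3(c(1, 1, 0), 25)
  tr <- c(10, -40, 7)
  ip2 <- place(transform_phantom(ph, R, tr))
  for (nm in c("S", "M", "L")) {
    moved <- as.numeric(R %*% ip1[[nm]] + tr)
    expect_lt(sqrt(sum((ip2[[nm]] - moved)^2)), 1e-5)
  }
})
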