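test_that("STL and PLY round-trips preserve geometry and topology", {
  ph <- generate_strip_phantom(strip_phantom_spec(20, 60, 40, 10, 20))
  for (fmt in c("stl", "stl_ascii", "ply")) {
    path <- tempfile(fileext = if (fmt == "ply") ".ply" else ".stl")
    write_mesh(ph$mesh, path, format = fmt)
    back <- read_mesh(path)
    expect_equal(nrow(back$vertices), ph$ground_truth$n_vertices)
    expect_equal(nrow(back$faces), ph$ground_truth$n_faces)
    expect_equal(mesh_volume(back), mesh_volume(ph$mesh), tolerance = 1e-5)
    # same vertex set up to ordering
    ref <- ph$mesh$vertices[order(ph$mesh$vertices[, 1],
                                  ph$mesh$vertices[, 2],
                                  ph$mesh$vertices[, 3]), ]
    got <- back$vertices[order(back$vertices[, 1], back$vertices[, 2],
                               back$vertices[, 3]), ]
    expect_lt(max(abs(ref - got)), 1e-6)
    unlink(path)
  }
})

test_that("unreadable or empty mesh files raise format errors", {
  p <- tempfile(fileext = ".stl")
  file.create(p)
  expect_error(read_mesh(p), "empty file")
  writeLines("not a mesh at all", p)
  expect_error(read_mesh(p), "format error")
  expect_error(read_mesh(tempfile(fileext = ".xyz")), "not found")
  unlink(p)
})

test_that("validate_mesh flags open edges and agrees with edge incidence", {
  cube <- generate_strip_phantom(strip_phantom_spec(20, 20, 20, 10, 10))$mesh
  rep <- validate_mesh(cube)
  expect_true(rep$watertight)
  expect_true(rep$consistent_winding)
  expect_true(rep$ok)
  holed <- surface_mesh(cube$vertices, cube$faces[-1, ], orient = FALSE)
  rep2 <- validate_mesh(holed)
  expect_false(rep2$watertight)
  expect_equal(rep2$n_open_edges, 3L)
  expect_match(rep2$failures, "not watertight", all = FALSE)
  # independent incidence count: every edge of the intact cube occurs twice
  f <- cube$faces
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  expect_true(all(table(key) == 2))
})

test_that("pubis phantom mesh passes all validation checks", {
  rep <- validate_mesh(default_pubis()$mesh)
  expect_true(rep$ok)
})

test_that("landmark JSON round-trips and schema errors are raised", {
  ph <- default_pubis()
  path <- tempfile(fileext = ".json")
  write_landmarks(ph$landmarks, path)
  back <- read_landmarks(path)
  for (nm in names(ph$landmarks)) {
    expect_lt(max(abs(as_matrix <- rbind(back[[nm]]) - rbind(ph$landmarks[[nm]]))),
              1e-9)
  }
  # missing required landmark
  lst <- jsonlite::fromJSON(path)
  lst$symphysis_lowest_O <- NULL
  p2 <- tempfile(fileext = ".json")
  jsonlite::write_json(lst, p2, digits = NA)
  expect_error(read_landmarks(p2), "schema error.*symphysis_lowest_O")
  unlink(c(path, p2))
})

test_that("landmarks snap to the surface and far points are rejected", {
  ph <- default_pubis()
  lm <- ph$landmarks
  snapped <- snap_landmarks(lm, ph$mesh)
  pts <- rbind(snapped$brim, snapped$obturator_loop)
  d <- sqrt(rowSums((pts -
    closest_on_mesh(ph$mesh, pts)$points)^2))
  expect_lt(max(d), 1e-6)
  lm$tubercle_apex <- lm$tubercle_apex + c(0, 25, 0)
  expect_error(snap_landmarks(lm, ph$mesh), "landmark error.*tubercle_apex")
})
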