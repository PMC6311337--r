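test_that("pubis phantom generation is deterministic for a fixed spec", {
  spec <- pubis_phantom_spec(ramus_length = 50, symphysis_height = 40, seed = 3)
  a <- generate_pubis_phantom(spec)
  b <- generate_pubis_phantom(spec)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  expect_identical(a$landmarks$brim, b$landmarks$brim)
})

test_that("phantom landmarks sit on the surface and encode the spec", {
  spec <- pubis_phantom_spec(symphysis_height = 44)
  ph <- generate_pubis_phantom(spec)
  lm <- snap_landmarks(ph$landmarks, ph$mesh)  # errors if > 1 mm off-surface
  d <- symphysis_vertical_distance(lm)
  expect_equal(d, 44, tolerance = 0.1 / 44)
  loop <- lm$obturator_loop
  expect_lt(max(abs(loop[1, ] - loop[nrow(loop), ])), 1e-6)
  # brim ordered medial -> lateral: distance from O increases
  O <- lm$symphysis_lowest_O
  dO <- sqrt(rowSums((lm$brim - matrix(O, nrow(lm$brim), 3, byrow = TRUE))^2))
  expect_gt(dO[length(dO)], dO[1])
})

test_that("phantom spec invariants are enforced", {
  expect_error(pubis_phantom_spec(ramus_length = -5), "parameter error")
  expect_error(pubis_phantom_spec(body_thickness_profile = c(3, 2)),
               "parameter error")
  # hole too large for the bone
  expect_error(generate_pubis_phantom(
    pubis_phantom_spec(ramus_length = 36, obturator_radius = 16)),
    "generation error")
})

test_that("cohort sampling is reproducible and recovers configured means", {
  cs <- cohort_spec(40, 40, seed = 1)
  a <- sample_cohort(cs)
  b <- sample_cohort(cs)
  expect_identical(a$manifest, b$manifest)
  expect_equal(nrow(a$manifest), 80)
  dist <- cohort_default_distributions()
  for (sx in c("male", "female")) {
    r <- dist[dist$parameter == "intertubercular_distance", ]
    mu <- if (sx == "male") r$mean_male else r$mean_female
    sd_ <- if (sx == "male") r$sd_male else r$sd_female
    got <- mean(a$manifest$intertubercular_distance[a$manifest$sex == sx])
    expect_lt(abs(got - mu), 3 * sd_ / sqrt(40))
  }
  expect_error(cohort_spec(0, 40), "parameter error")
})

test_that("a different seed changes the draws but not the schema", {
  a <- sample_cohort(cohort_spec(5, 5, seed = 1))
  b <- sample_cohort(cohort_spec(5, 5, seed = 2))
  expect_identical(names(a$manifest), names(b$manifest))
  expect_false(isTRUE(all.equal(a$manifest$ramus_length,
                                b$manifest$ramus_length)))
})

test_that("wedge phantoms and tubes are watertight", {
  for (ap in c(120, 40, NA)) {
    expect_true(validate_mesh(generate_wedge_phantom(ap)$mesh)$ok)
  }
  expect_true(validate_mesh(tube_mesh(5, 40, 48))$ok)
})
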