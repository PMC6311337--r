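test_that("the two pelvimetric distances are plain Euclidean distances", {
  ph <- default_pubis()
  lm <- ph$landmarks
  lm$tubercle_apex <- c(0, 0, 0)
  lm$contralateral_tubercle_apex <- c(60, 0, 0)
  expect_equal(intertubercular_distance(lm), 60)
  lm$symphysis_upper <- c(0, 0, 0)
  lm$symphysis_lower <- c(0, 0, -40)
  expect_equal(symphysis_vertical_distance(lm), 40)
  expect_equal(symphysis_vertical_distance(lm, method = "projected"), 40)
  lm$contralateral_tubercle_apex <- NULL
  expect_error(intertubercular_distance(lm), "missing-landmark")
  lm$symphysis_lower <- lm$symphysis_upper
  expect_warning(d <- symphysis_vertical_distance(lm), "degenerate-landmark")
  expect_equal(d, 0)
})

test_that("both distances are rigid-motion invariant", {
  ph <- default_pubis()
  lm1 <- ph$landmarks
  lm2 <- transform_phantom(ph, rotation3(c(0, 1, 1), 77), c(-3, 8, 120))$landmarks
  expect_equal(intertubercular_distance(lm1), intertubercular_distance(lm2),
               tolerance = 1e-12)
  expect_equal(symphysis_vertical_distance(lm1),
               symphysis_vertical_distance(lm2), tolerance = 1e-12)
})

test_that("phantom cohorts recover the configured intertubercular means", {
  man <- sample_cohort(cohort_spec(40, 40, seed = 5))$manifest
  # measure through the landmark route on a few subjects
  sc <- sample_cohort(cohort_spec(3, 1, seed = 5))
  for (sub in sc$subjects[1:3]) {
    ph <- generate_pubis_phantom(sub$spec)
    expect_equal(intertubercular_distance(ph$landmarks),
                 sub$spec$intertubercular_distance, tolerance = 1e-9)
  }
  expect_lt(abs(mean(man$intertubercular_distance[man$sex == "male"]) - 58.40),
            3 * 6.03 / sqrt(40))
  expect_lt(abs(mean(man$intertubercular_distance[man$sex == "female"]) - 61.98),
            3 * 9.04 / sqrt(40))
})
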