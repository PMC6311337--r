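test_that("full hemipelvis analysis satisfies the result invariants", {
  res <- default_pubis_result()
  expect_gte(res$inner$MAIA, 0)
  expect_lte(res$inner$MPIA, 0)
  expect_gt(res$inner$MAIA, res$inner$MPIA)
  expect_gte(res$outer$MAIA, 0)
  expect_lte(res$outer$MPIA, 0)
  expect_gte(res$inner$L1, 14)
  expect_gte(res$outer$L2, 14)
  expect_gte(res$tangential$L0, 14)
  expect_gte(res$inner$plane_MIA, 0)
  expect_lt(res$inner$plane_MIA, 90)
  expect_true(res$region$pattern %in% c("blunt_V", "sharp_V", "disjoint"))
  df <- as.data.frame(res)
  expect_equal(nrow(df), 1)
  expect_true(all(is.finite(unlist(df[vapply(df, is.numeric, logical(1))]))))
})

test_that("analysis is deterministic for fixed inputs", {
  ph <- default_pubis()
  r1 <- analyze_hemipelvis(ph$mesh, ph$landmarks)
  r2 <- analyze_hemipelvis(ph$mesh, ph$landmarks)
  expect_identical(numeric_result_row(r1), numeric_result_row(r2))
})

test_that("stage errors carry the stage name", {
  ph <- default_pubis()
  lm <- ph$landmarks
  lm$tubercle_edge_m <- lm$tubercle_edge_m +
    matrix(c(0, 0, -30), nrow(lm$tubercle_edge_m), 3, byrow = TRUE)
  expect_error(snap_landmarks(lm, ph$mesh), "landmark error")
  long_plate <- corridor_config(plate = plate_spec(hole_pitch = 200))
  expect_error(analyze_hemipelvis(ph$mesh, ph$landmarks, long_plate),
               "plate_placement")
})
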