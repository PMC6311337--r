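test_that("pooled t from summaries matches t from raw data exactly", {
  set.seed(42)
  x <- rnorm(23, 10, 2)
  y <- rnorm(31, 11.5, 2.6)
  g1 <- group_summary(mean(x), sd(x), length(x))
  g2 <- group_summary(mean(y), sd(y), length(y))
  ours <- two_sample_t_from_summaries(g1, g2)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})

test_that("printed outer-screw length summaries reproduce t = 4.139", {
  tt <- two_sample_t_from_summaries(group_summary(55.71, 6.36, 40),
                                    group_summary(48.68, 8.65, 40))
  expect_equal(tt$t, 4.139, tolerance = 0.02 / 4.139)
  expect_equal(tt$df, 78)
})

test_that("identical groups give t = 0, p = 1; degenerate sds error", {
  g <- group_summary(5, 1, 10)
  tt <- two_sample_t_from_summaries(g, g)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  z <- group_summary(5, 0, 10)
  expect_error(two_sample_t_from_summaries(z, z), "undefined-t")
})

test_that("for equal n the pooled t equals the Welch t statistic", {
  g1 <- group_summary(12.3, 3.1, 40)
  g2 <- group_summary(10.9, 5.2, 40)
  pooled <- two_sample_t_from_summaries(g1, g2)$t
  welch_se <- sqrt(g1$sd^2 / g1$n + g2$sd^2 / g2$n)
  expect_equal(pooled, (g1$mean - g2$mean) / welch_se, tolerance = 1e-12)
})

test_that("pool_groups is symmetric and agrees with concatenated raw data", {
  set.seed(7)
  x <- rnorm(17, 3, 1.2)
  y <- rnorm(29, 5, 2.1)
  g1 <- group_summary(mean(x), sd(x), length(x))
  g2 <- group_summary(mean(y), sd(y), length(y))
  p12 <- pool_groups(g1, g2)
  p21 <- pool_groups(g2, g1)
  expect_equal(p12$mean, p21$mean, tolerance = 1e-12)
  expect_equal(p12$sd, p21$sd, tolerance = 1e-12)
  expect_equal(p12$mean, mean(c(x, y)), tolerance = 1e-9)
  expect_equal(p12$sd, sd(c(x, y)), tolerance = 1e-9)
  # closed form: pooling a group with itself
  g <- group_summary(10, 2, 15)
  self <- pool_groups(g, g)
  expect_equal(self$mean, 10)
  expect_equal(self$sd, 2 * sqrt((2 * 15 - 2) / (2 * 15 - 1)), tolerance = 1e-12)
})

test_that("KS screen accepts normal samples and rejects uniform ones", {
  ok <- 0; rej <- 0
  for (i in 1:40) {
    set.seed(100 + i)
    ok <- ok + (ks_normality(rnorm(1000, 5, 2))$p > 0.05)
    rej <- rej + (ks_normality(runif(1000))$p < 0.05)
  }
  expect_gte(ok, 38)   # >= 95% acceptance under the null
  expect_gte(rej, 38)  # >= 95% power under gross non-normality
  expect_error(ks_normality(c(1, 2, 3)), "sample-size")
  expect_error(ks_normality(rep(1, 10)), "degenerate-sd")
})

test_that("the audit reproduces the printed-table consistency partition", {
  audit <- audit_printed_tables()
  bad <- audit[!audit$consistent, ]
  expect_equal(nrow(bad), 2)
  expect_setequal(paste(bad$table, bad$parameter),
                  c("tangential Screw Length", "tangential APIA"))
  good <- audit[audit$consistent, ]
  expect_lt(max(good$discrepancy), 0.02)
  expect_gt(min(bad$discrepancy), 0.5)
})

test_that("make_tables builds the three-table report with t and p rows", {
  set.seed(9)
  n <- 12
  df <- data.frame(
    sex = rep(c("male", "female"), each = n),
    inner_L1 = rnorm(2 * n, 46, 4), inner_MAIA = rnorm(2 * n, 12, 9),
    inner_MPIA = rnorm(2 * n, -12, 10),
    outer_L2 = c(rnorm(n, 55, 6), rnorm(n, 49, 8)),
    outer_MAIA = rnorm(2 * n, 10, 9), outer_MPIA = rnorm(2 * n, -9, 10),
    tangential_L0 = rnorm(2 * n, 50, 10), tangential_MIA = rnorm(2 * n, 31, 9),
    tangential_APIA = rnorm(2 * n, 7, 10))
  rep_ <- make_tables(df)
  expect_setequal(unique(rep_$table), c("inner", "outer", "tangential"))
  expect_equal(nrow(rep_), 9)
  expect_true(all(c("t", "p", "total_mean", "total_sd") %in% names(rep_)))
  # identical subjects -> all t = 0
  df0 <- df
  num <- vapply(df0, is.numeric, logical(1))
  df0[num] <- lapply(df0[num], function(x) rep(1.5, length(x)))
  expect_true(all(make_tables(df0)$t == 0))
  expect_error(make_tables(df[df$sex == "male", ]), "stratification")
  txt <- format_tables(rep_)
  expect_true(any(grepl("Total \\(n=24\\)", txt)))
})
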