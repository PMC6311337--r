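# Cohort statistics: pooled two-sample t from summaries, group pooling, KS
# normality screen, the three-table report and the printed-table audit.

#' Group summary (mean, sd, n)
#'
#' @param mean group mean; `sd` standard deviation; `n` group size.
#' @return a `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (n < 2) stop("parameter error: group needs n >= 2", call. = FALSE)
  if (sd < 0) stop("parameter error: sd must be >= 0", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group_summary: mean %.3f, sd %.3f, n %d\n", x$mean, x$sd, x$n))
  invisible(x)
}

#' Pooled-variance two-sample t test from group summaries
#'
#' Student's t with the pooled variance
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`,
#' `t = (m1 - m2) / sqrt(sp^2 (1/n1 + 1/n2))`, `df = n1 + n2 - 2`, two-sided
#' p.  The sign follows `m1 - m2` (convention: group 1 = male).
#'
#' @param g1,g2 [group_summary()] objects (or lists with mean/sd/n).
#' @return list with `t`, `df`, `p`, `pooled_sd`.
#' @export
two_sample_t_from_summaries <- function(g1, g2) {
  n1 <- g1$n; n2 <- g2$n
  sp2 <- ((n1 - 1) * g1$sd^2 + (n2 - 1) * g2$sd^2) / (n1 + n2 - 2)
  if (sp2 <= 0) {
    if (abs(g1$mean - g2$mean) < 1e-12) {
      stop("undefined-t error: zero variance and equal means", call. = FALSE)
    }
    return(list(t = sign(g1$mean - g2$mean) * Inf, df = n1 + n2 - 2, p = 0,
                pooled_sd = 0))
  }
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (g1$mean - g2$mean) / se
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df), pooled_sd = sqrt(sp2))
}

#' Pool two group summaries
#'
#' Exact two-group pooling: combined mean is the size-weighted mean and the
#' combined variance adds the between-group spread to the within-group sum
#' of squares.
#'
#' @param g1,g2 [group_summary()] objects.
#' @return a [group_summary()] of the combined group.
#' @export
pool_groups <- function(g1, g2) {
  n <- g1$n + g2$n
  m <- (g1$n * g1$mean + g2$n * g2$mean) / n
  ss <- (g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2 +
    g1$n * (g1$mean - m)^2 + g2$n * (g2$mean - m)^2
  group_summary(mean = m, sd = sqrt(ss / (n - 1)), n = n)
}

#' One-sample Kolmogorov-Smirnov normality screen
#'
#' KS statistic of the sample against a normal with the sample's own mean
#' and sd, with the asymptotic p value.  Because the parameters are
#' estimated from the same sample, the p value is conservative (a Lilliefors
#' correction would reject more often); the screen mirrors the common
#' SPSS-style workflow.
#'
#' @param sample numeric vector, `n >= 5`.
#' @return list with `D`, `p`, `n`.
#' @export
ks_normality <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 5) {
    stop("sample-size error: KS screen needs n >= 5", call. = FALSE)
  }
  s <- sd(sample)
  if (s < 1e-12) {
    stop("degenerate-sd error: constant sample", call. = FALSE)
  }
  kt <- suppressWarnings(ks.test(sample, "pnorm", mean = mean(sample), sd = s))
  list(D = unname(kt$statistic), p = kt$p.value, n = length(sample))
}

#' The printed per-sex summary tables of record
#'
#' The per-sex (mean, sd, n = 40) triples and printed t values of the three
#' published measurement tables (inner screw, outer screw,
#' obturator-tangential screw), shipped as plain-text package data.
#'
#' @return data frame with columns `table`, `parameter`, `mean_male`,
#'   `sd_male`, `mean_female`, `sd_female`, `n_male`, `n_female`,
#'   `t_printed`, `total_mean_printed`, `total_sd_printed`.
#' @export
printed_reference_tables <- function() {
  path <- system.file("extdata", "printed_reference_tables.csv",
                      package = "pubicorridor", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Audit printed t values against their own summaries
#'
#' Recomputes every between-sex t from the printed per-sex summaries and
#' flags entries whose printed t cannot be reproduced (absolute discrepancy
#' above `flag_above`).  Discrepant printed values are reported, never
#' corrected.
#'
#' @param tables data frame in the layout of [printed_reference_tables()].
#' @param flag_above discrepancy (absolute) that flags an entry.
#' @return data frame with recomputed `t_recomputed`, `discrepancy`,
#'   `consistent`, pooled totals and their discrepancies.
#' @export
audit_printed_tables <- function(tables = printed_reference_tables(),
                                 flag_above = 0.5) {
  out <- tables
  out$t_recomputed <- NA_real_
  out$total_mean_recomputed <- NA_real_
  out$total_sd_recomputed <- NA_real_
  for (i in seq_len(nrow(tables))) {
    g1 <- group_summary(tables$mean_male[i], tables$sd_male[i],
                        tables$n_male[i])
    g2 <- group_summary(tables$mean_female[i], tables$sd_female[i],
                        tables$n_female[i])
    out$t_recomputed[i] <- two_sample_t_from_summaries(g1, g2)$t
    pooled <- pool_groups(g1, g2)
    out$total_mean_recomputed[i] <- pooled$mean
    out$total_sd_recomputed[i] <- pooled$sd
  }
  out$discrepancy <- abs(out$t_recomputed - out$t_printed)
  out$consistent <- out$discrepancy <= flag_above
  out
}

#' Per-parameter three-table cohort report
#'
#' Builds the three measurement tables (inner screw: length L1, MAIA, MPIA;
#' outer screw: length L2, MAIA, MPIA; tangential screw: length L0, MIA,
#' APIA) from per-subject corridor results: per-sex mean +/- sd, pooled
#' total, pooled-variance t and two-sided p, significance at 0.05.
#'
#' @param results data frame with one row per subject including a `sex`
#'   column (`"male"`/`"female"`) and the columns of
#'   [as.data.frame.corridor_result()].
#' @return data frame with one row per (table, parameter).
#' @export
make_tables <- function(results) {
  stopifnot(is.data.frame(results), "sex" %in% names(results))
  for (sx in c("male", "female")) {
    if (sum(results$sex == sx) < 2) {
      stop("stratification error: need at least 2 subjects per sex",
           call. = FALSE)
    }
  }
  layout <- list(
    inner = c("Screw Length" = "inner_L1", MAIA = "inner_MAIA",
              MPIA = "inner_MPIA"),
    outer = c("Screw Length" = "outer_L2", MAIA = "outer_MAIA",
              MPIA = "outer_MPIA"),
    tangential = c("Screw Length" = "tangential_L0", MIA = "tangential_MIA",
                   APIA = "tangential_APIA"))
  rows <- list()
  for (tab in names(layout)) {
    for (par in names(layout[[tab]])) {
      col <- layout[[tab]][[par]]
      if (!col %in% names(results)) next
      xm <- results[results$sex == "male", col]
      xf <- results[results$sex == "female", col]
      xm <- xm[is.finite(xm)]; xf <- xf[is.finite(xf)]
      if (length(xm) < 2 || length(xf) < 2) next
      g1 <- group_summary(mean(xm), sd(xm), length(xm))
      g2 <- group_summary(mean(xf), sd(xf), length(xf))
      # identical degenerate strata are reported as no difference
      tt <- tryCatch(two_sample_t_from_summaries(g1, g2),
                     error = function(e) list(t = 0, df = g1$n + g2$n - 2,
                                              p = 1))
      pooled <- pool_groups(g1, g2)
      rows[[length(rows) + 1]] <- data.frame(
        table = tab, parameter = par,
        mean_male = g1$mean, sd_male = g1$sd, n_male = g1$n,
        mean_female = g2$mean, sd_female = g2$sd, n_female = g2$n,
        total_mean = pooled$mean, total_sd = pooled$sd, total_n = pooled$n,
        t = tt$t, df = tt$df, p = tt$p, significant = tt$p < 0.05,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Plain-text rendering of the three-table report
#'
#' @param report output of [make_tables()].
#' @return character vector of report lines (means/sds to 2 decimals, t to
#'   3, mirroring the published layout).
#' @export
format_tables <- function(report) {
  lines <- character()
  for (tab in unique(report$table)) {
    sub <- report[report$table == tab, ]
    lines <- c(lines, sprintf("Measured parameters for the %s screw (mean+-sd)",
                              tab))
    hdr <- sprintf("%-14s %s", "Gender",
                   paste(sprintf("%-20s", sub$parameter), collapse = ""))
    lines <- c(lines, hdr)
    fmt_row <- function(label, m, s) {
      sprintf("%-14s %s", label,
              paste(sprintf("%-20s", sprintf("%.2f+-%.2f", m, s)),
                    collapse = ""))
    }
    lines <- c(lines,
               fmt_row(sprintf("Male (n=%d)", sub$n_male[1]),
                       sub$mean_male, sub$sd_male),
               fmt_row(sprintf("Female (n=%d)", sub$n_female[1]),
                       sub$mean_female, sub$sd_female),
               fmt_row(sprintf("Total (n=%d)", sub$total_n[1]),
                       sub$total_mean, sub$total_sd),
               sprintf("%-14s %s", "t value",
                       paste(sprintf("%-20s", sprintf("%.3f", sub$t)),
                             collapse = "")),
               sprintf("%-14s %s", "P value",
                       paste(sprintf("%-20s",
                                     ifelse(sub$p < 0.001, "<0.001",
                                            ifelse(sub$p < 0.05, "<0.05",
                                                   ">0.05"))),
                             collapse = "")),
               "")
  }
  lines
}
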