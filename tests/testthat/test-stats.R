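test_that("percentile outlier exclusion trims strictly outside P10/P90", {
  r <- exclude_outliers(0:10)
  expect_identical(sort(r$values), as.numeric(1:9))   # P10 = 1, P90 = 9
  expect_identical(r$excluded, 2L)
  same <- exclude_outliers(rep(5, 8))
  expect_identical(same$excluded, 0L)
  expect_warning(tiny <- exclude_outliers(c(1, 2)), "fewer")
  expect_identical(tiny$excluded, 0L)
})

test_that("paired t matches the closed form and is shift invariant", {
  x <- c(10, 12, 14, 16, 18, 20)
  y <- x - c(1, 2, 3, 4, 5, 6)
  st <- paired_t(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(6))
  p_hand <- 2 * pt(-abs(t_hand), 5)
  expect_equal(st$statistic, t_hand, tolerance = 1e-10)
  expect_equal(st$p_value, p_hand, tolerance = 1e-10)
  expect_equal(st$estimate, 3.5, tolerance = 1e-12)
  expect_identical(st$df1, 5)
  sh <- paired_t(x + 100, y + 100)
  expect_equal(sh$p_value, st$p_value, tolerance = 1e-12)
  eq <- paired_t(x, x)
  expect_identical(eq$p_value, 1)
  expect_identical(eq$statistic, 0)
})

test_that("two-condition repeated-measures ANOVA is the squared paired t", {
  set.seed(61)
  df <- tibble::tibble(
    subject = rep(1:6, each = 2),
    condition = rep(c("RV", "LV"), 6),
    value = rnorm(12, 300, 15))
  rm <- rm_anova(df, "value", "condition", "subject")
  w <- tidyr::pivot_wider(df, names_from = condition, values_from = value)
  pt_ <- paired_t(w$RV, w$LV)
  expect_equal(rm$statistic, pt_$statistic^2, tolerance = 1e-9)
  expect_equal(rm$p_value, pt_$p_value, tolerance = 1e-9)
  expect_error(rm_anova(df[-1, ], "value", "condition", "subject"), "unbalanced_anova")
})

test_that("repeated-measures ANOVA matches textbook sums of squares on a 3x2 table", {
  df <- tibble::tibble(
    subject = rep(1:3, each = 2),
    condition = rep(c("A", "B"), 3),
    value = c(10, 14, 12, 13, 9, 15))
  rm <- rm_anova(df, "value", "condition", "subject")
  grand <- mean(df$value)
  ss_cond <- 3 * sum((tapply(df$value, df$condition, mean) - grand)^2)
  ss_subj <- 2 * sum((tapply(df$value, df$subject, mean) - grand)^2)
  ss_tot <- sum((df$value - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f_hand <- (ss_cond / 1) / (ss_err / 2)
  expect_equal(rm$statistic, f_hand, tolerance = 1e-10)
  expect_identical(c(rm$df1, rm$df2), c(1, 2))
})

test_that("unbalanced one-way ANOVA matches the textbook formula", {
  g1 <- c(1, 2, 3); g2 <- c(2, 3, 4, 5)
  st <- unbalanced_anova(c(g1, g2), c(rep("a", 3), rep("b", 4)))
  grand <- mean(c(g1, g2))
  ssb <- 3 * (mean(g1) - grand)^2 + 4 * (mean(g2) - grand)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f_hand <- (ssb / 1) / (ssw / 5)
  expect_equal(st$statistic, f_hand, tolerance = 1e-10)
  expect_equal(st$p_value, 1 - pf(f_hand, 1, 5), tolerance = 1e-10)
  # two groups: F equals the squared equal-variance t
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(st$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_error(unbalanced_anova(c(1, 1, 2), c("a", "a", "b")), "fewer than 2")
})

test_that("Pearson correlation with t test matches the closed form", {
  x <- c(1, 3, 4, 6, 8, 9, 11, 14)
  y <- c(2, 4, 5, 9, 8, 12, 12, 16)
  st <- pearson_with_t(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((8 - 2) / (1 - r_hand^2))
  expect_equal(st$estimate, r_hand, tolerance = 1e-10)
  expect_equal(st$statistic, t_hand, tolerance = 1e-10)
  expect_equal(st$p_value, 2 * pt(-abs(t_hand), 6), tolerance = 1e-10)
  lin <- pearson_with_t(x, 2 * x + 1)
  expect_equal(lin$estimate, 1, tolerance = 1e-12)
  expect_error(pearson_with_t(x, rep(3, 8)), "variance")
})

test_that("tidy and glance return one-row summaries", {
  st <- paired_t(c(1, 2, 3, 4), c(0, 1, 5, 2))
  td <- tidy(st)
  expect_identical(nrow(td), 1L)
  expect_identical(td$test, "paired_t")
  expect_identical(td, glance(st))
})

test_that("the study battery produces every designed comparison", {
  set.seed(62)
  base <- tidyr::crossing(pig = 1:6, cycle_length = c(500, 300),
                          pacing_chamber = "RV",
                          tissue_class = c("aLGE", "healthy"),
                          field = c("ari", "rt"))
  lv <- dplyr::mutate(dplyr::filter(base, pig <= 4), pacing_chamber = "LV")
  summ <- dplyr::bind_rows(base, lv)
  summ$case_id <- paste0("pig", summ$pig, "_", summ$pacing_chamber, "_", summ$cycle_length)
  summ$n_sites <- 100L
  summ$mean_ms <- rnorm(nrow(summ), 300, 15)
  summ$sd_ms <- abs(rnorm(nrow(summ), 20, 5))
  summ$mean_gradient_ms_mm <- abs(rnorm(nrow(summ), 5, 2))
  dmap <- setNames(runif(length(unique(summ$case_id)), 2, 18), unique(summ$case_id))
  summ$pacing_distance_mm <- unname(dmap[summ$case_id])
  summ$pacing_class <- ifelse(summ$pacing_distance_mm <= 10, "<=10mm", ">10mm")
  res <- run_study_stats(summ, exclude = FALSE)
  expect_true(all(c(
    "mean_ari_aLGE_vs_healthy_500ms", "mean_ari_aLGE_vs_healthy_300ms",
    "ari_heterogeneity_aLGE_vs_healthy_500ms",
    "ari_gradient_aLGE_vs_healthy_all_cl", "rt_gradient_aLGE_vs_healthy_all_cl",
    "ari_mean_RV_vs_LV_aLGE", "ari_heterogeneity_RV_vs_LV_healthy",
    "ari_gradient_RV_vs_LV_aLGE", "rt_gradient_RV_vs_LV_healthy",
    "ari_gradient_vs_pacing_distance", "ari_gradient_pacing_le10_vs_gt10",
    "rt_gradient_vs_pacing_distance", "rt_gradient_pacing_le10_vs_gt10"
  ) %in% res$comparison))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  # permuting case order leaves every p unchanged
  perm <- summ[sample(nrow(summ)), ]
  res2 <- run_study_stats(perm, exclude = FALSE)
  m <- match(res$comparison, res2$comparison)
  expect_equal(res$p_value, res2$p_value[m], tolerance = 1e-12)
})
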