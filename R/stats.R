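#' Percentile-based outlier exclusion
#'
#' Removes values strictly below the 10th or strictly above the 90th
#' percentile of the data group (percentiles by linear interpolation
#' between order statistics, `stats::quantile` type 7). Applied once per
#' group, never iteratively. Groups with fewer than 3 values are returned
#' unchanged with a warning.
#'
#' @param x Numeric vector.
#' @param probs Lower/upper percentile bounds (default `c(0.10, 0.90)`).
#' @return List: `values` (retained), `keep` (logical index into `x`),
#'   `excluded` (count).
#' @export
exclude_outliers <- function(x, probs = c(0.10, 0.90)) {
  x <- as.numeric(x)
  if (length(x) < 3) {
    warn("fewer than 3 values; outlier exclusion skipped")
    return(list(values = x, keep = rep(TRUE, length(x)), excluded = 0L))
  }
  q <- quantile(x, probs, type = 7, names = FALSE, na.rm = TRUE)
  keep <- !is.na(x) & x >= q[1] & x <= q[2]
  list(values = x[keep], keep = keep, excluded = sum(!keep))
}

new_ari_stat <- function(test_name, estimate, statistic, df1, df2 = NA_real_,
                         p_value, n, excluded_outliers = 0L) {
  structure(list(
    test_name = test_name, estimate = estimate, statistic = statistic,
    df1 = df1, df2 = df2, p_value = p_value, n = n,
    excluded_outliers = as.integer(excluded_outliers)),
    class = "ari_stat")
}

#' @export
print.ari_stat <- function(x, ...) {
  cat(sprintf("<ari_stat> %s: estimate %.4g, statistic %.4g, df %s, p %.4g (n=%d, %d outliers excluded)\n",
              x$test_name, x$estimate, x$statistic,
              if (is.na(x$df2)) sprintf("%g", x$df1) else sprintf("%g,%g", x$df1, x$df2),
              x$p_value, x$n, x$excluded_outliers))
  invisible(x)
}

#' @export
tidy.ari_stat <- function(x, ...) {
  tibble::tibble(
    test = x$test_name, estimate = x$estimate, statistic = x$statistic,
    df1 = x$df1, df2 = x$df2, p_value = x$p_value, n = x$n,
    excluded_outliers = x$excluded_outliers)
}

#' @export
glance.ari_stat <- function(x, ...) tidy(x)

# apply per-arm outlier exclusion to paired vectors; a pair survives only
# when both members are retained in their own data group
exclude_pairs <- function(x, y, exclude) {
  if (!exclude) return(list(x = x, y = y, excluded = 0L))
  kx <- exclude_outliers(x)$keep
  ky <- exclude_outliers(y)$keep
  keep <- kx & ky
  list(x = x[keep], y = y[keep], excluded = sum(!keep))
}

#' Paired Student t test
#'
#' Two-sided paired t test (`t = mean(d) / (sd(d)/sqrt(n))`, `df = n-1`),
#' with optional percentile outlier exclusion applied to each arm (a pair
#' is dropped when either member is an outlier in its own group, so
#' pairing is preserved).
#'
#' @param x,y Paired numeric vectors (same cases, same order).
#' @param exclude Apply [exclude_outliers()] first?
#' @return An `ari_stat`; estimate is the mean difference `x - y`.
#' @export
paired_t <- function(x, y, exclude = FALSE) {
  if (length(x) != length(y)) abort("paired vectors must have equal length.")
  ex <- exclude_pairs(x, y, exclude)
  x <- ex$x; y <- ex$y
  n <- length(x)
  if (n < 2) abort("paired t test needs at least 2 pairs.")
  d <- x - y
  if (all(d == 0)) {
    return(new_ari_stat("paired_t", 0, 0, n - 1, p_value = 1, n = n,
                        excluded_outliers = ex$excluded))
  }
  ht <- t.test(x, y, paired = TRUE)
  new_ari_stat("paired_t", estimate = unname(ht$estimate),
               statistic = unname(ht$statistic), df1 = unname(ht$parameter),
               p_value = ht$p.value, n = n, excluded_outliers = ex$excluded)
}

#' One-factor repeated-measures ANOVA
#'
#' Within-subject one-factor ANOVA (no sphericity correction): the
#' condition effect is tested against the subject-by-condition residual.
#' With two conditions the F statistic is exactly the squared paired-t
#' statistic. Requires a complete subject x condition table.
#'
#' @param data Data frame.
#' @param value,condition,subject Column names (strings).
#' @param exclude Apply per-condition outlier exclusion first (subjects
#'   with any excluded cell are dropped)?
#' @return An `ari_stat`; estimate is the F statistic.
#' @export
rm_anova <- function(data, value, condition, subject, exclude = FALSE) {
  df <- tibble::tibble(
    value = as.numeric(data[[value]]),
    condition = factor(data[[condition]]),
    subject = factor(data[[subject]]))
  tab <- table(df$subject, df$condition)
  if (any(tab != 1)) {
    abort("incomplete subject x condition table; use unbalanced_anova for unequal groups.")
  }
  excluded <- 0L
  if (exclude) {
    keep <- rep(TRUE, nrow(df))
    for (cond in levels(df$condition)) {
      sel <- df$condition == cond
      keep[sel] <- keep[sel] & exclude_outliers(df$value[sel])$keep
    }
    bad_subj <- unique(df$subject[!keep])
    excluded <- length(bad_subj)
    df <- df[!df$subject %in% bad_subj, , drop = FALSE]
    df$subject <- droplevels(df$subject)
  }
  if (nlevels(df$subject) < 2 || nlevels(df$condition) < 2) {
    abort("repeated-measures ANOVA needs >= 2 subjects and >= 2 conditions.")
  }
  fit <- aov(value ~ condition + Error(subject), data = df)
  s <- summary(fit)
  within <- s[["Error: Within"]][[1]]
  Fv <- within["condition", "F value"]
  p <- within["condition", "Pr(>F)"]
  new_ari_stat("rm_anova", estimate = Fv, statistic = Fv,
               df1 = within["condition", "Df"],
               df2 = within["Residuals", "Df"],
               p_value = p, n = nlevels(df$subject),
               excluded_outliers = excluded)
}

#' One-way ANOVA for unequal group sizes
#'
#' Ordinary between-group one-way ANOVA, valid for unbalanced designs.
#' With two groups the F statistic equals the squared equal-variance
#' two-sample t statistic.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 groups, each with >= 2 values after
#'   any exclusion).
#' @param exclude Apply per-group outlier exclusion first?
#' @return An `ari_stat`; estimate is the F statistic.
#' @export
unbalanced_anova <- function(values, groups, exclude = FALSE) {
  df <- tibble::tibble(value = as.numeric(values), group = factor(groups))
  excluded <- 0L
  if (exclude) {
    keep <- rep(TRUE, nrow(df))
    for (gl in levels(df$group)) {
      sel <- df$group == gl
      keep[sel] <- exclude_outliers(df$value[sel])$keep
    }
    excluded <- sum(!keep)
    df <- df[keep, , drop = FALSE]
    df$group <- droplevels(df$group)
  }
  cnt <- table(df$group)
  if (length(cnt) < 2) abort("at least 2 groups are required.")
  if (any(cnt < 2)) {
    abort(sprintf("group '%s' has fewer than 2 values.",
                  names(cnt)[which(cnt < 2)[1]]))
  }
  a <- anova(lm(value ~ group, data = df))
  new_ari_stat("unbalanced_anova", estimate = a$`F value`[1],
               statistic = a$`F value`[1],
               df1 = a$Df[1], df2 = a$Df[2], p_value = a$`Pr(>F)`[1],
               n = nrow(df), excluded_outliers = excluded)
}

#' Pearson correlation with t test
#'
#' Two-sided test of `r` via `t = r * sqrt((n-2)/(1-r^2))`, `df = n-2`.
#'
#' @param x,y Numeric vectors (n >= 3, nonzero variance).
#' @param exclude Apply per-arm outlier exclusion (pairs preserved)?
#' @return An `ari_stat`; estimate is `r`.
#' @export
pearson_with_t <- function(x, y, exclude = FALSE) {
  if (length(x) != length(y)) abort("vectors must have equal length.")
  ex <- exclude_pairs(x, y, exclude)
  x <- ex$x; y <- ex$y
  if (length(x) < 3) abort("correlation needs at least 3 pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y.")
  ht <- cor.test(x, y, method = "pearson")
  new_ari_stat("pearson_t", estimate = unname(ht$estimate),
               statistic = unname(ht$statistic), df1 = unname(ht$parameter),
               p_value = ht$p.value, n = length(x),
               excluded_outliers = ex$excluded)
}

#' The study's statistical battery over region summaries
#'
#' Runs every headline comparison on a table of per-case region summaries
#' (one row per case x tissue class x field, as produced by
#' [case_region_summary()] across cases):
#'
#' * aLGE vs healthy mean ARI and ARI heterogeneity at each cycle length
#'   (paired t across pigs, RV maps);
#' * aLGE vs healthy ARI gradient, all cycle lengths together (paired t,
#'   pig x cycle-length units);
#' * RV vs LV pacing per tissue class and metric (repeated-measures
#'   ANOVA over the pigs mapped from both chambers);
#' * aLGE gradient vs pacing distance from scar (Pearson + t);
#' * pacing <=10 mm vs >10 mm from scar (unbalanced ANOVA on aLGE
#'   gradients);
#' * the gradient comparisons repeated for repolarization time.
#'
#' The percentile outlier rule operates on the site-level data groups
#' inside [run_case()]; `exclude = TRUE` additionally trims the
#' case-level arms here (with 6-value groups that always removes each
#' arm's min and max, so it is off by default). Comparisons whose design
#' cannot be formed from the data (too few cases) are flagged, not
#' fatal.
#'
#' @param summaries Region-summary tibble with columns `case_id`, `pig`,
#'   `pacing_chamber`, `cycle_length`, `tissue_class`, `field`,
#'   `mean_ms`, `sd_ms`, `mean_gradient_ms_mm`, `pacing_distance_mm`,
#'   `pacing_class`.
#' @param exclude Apply case-level outlier exclusion per arm?
#' @param alpha Significance level recorded alongside each row.
#' @return Tibble: `comparison`, `field`, plus [tidy()] columns of each
#'   test and a `note` column (NA when the test ran).
#' @export
run_study_stats <- function(summaries, exclude = FALSE, alpha = 0.05) {
  rows <- list()
  add <- function(comparison, field, stat_or_note) {
    row <- if (inherits(stat_or_note, "ari_stat")) {
      dplyr::mutate(tidy(stat_or_note), note = NA_character_)
    } else {
      tibble::tibble(test = NA_character_, estimate = NA_real_,
                     statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                     p_value = NA_real_, n = NA_integer_,
                     excluded_outliers = NA_integer_, note = stat_or_note)
    }
    row$comparison <- comparison; row$field <- field
    row$significant <- !is.na(row$p_value) & row$p_value < alpha
    rows[[length(rows) + 1]] <<- row
  }
  try_test <- function(comparison, field, expr) {
    res <- tryCatch(expr, error = function(e) conditionMessage(e))
    add(comparison, field, res)
  }
  pair_by_class <- function(df, col) {
    wide <- tidyr::pivot_wider(
      df[, c("case_id", "tissue_class", col)],
      names_from = "tissue_class", values_from = dplyr::all_of(col))
    wide[stats::complete.cases(wide), , drop = FALSE]
  }
  rv <- dplyr::filter(summaries, .data$pacing_chamber == "RV")

  ari <- dplyr::filter(rv, .data$field == "ari")
  for (cl in sort(unique(ari$cycle_length), decreasing = TRUE)) {
    sub <- dplyr::filter(ari, .data$cycle_length == cl)
    for (metric in c(mean_ari = "mean_ms", ari_heterogeneity = "sd_ms")) {
      w <- pair_by_class(sub, metric)
      nm <- names(which(c(mean_ari = "mean_ms", ari_heterogeneity = "sd_ms") == metric))
      try_test(sprintf("%s_aLGE_vs_healthy_%dms", nm, cl), "ari",
               if (nrow(w) >= 2) paired_t(w$aLGE, w$healthy, exclude = exclude)
               else stop("fewer than 2 complete pairs"))
    }
  }

  for (fld in c("ari", "rt")) {
    sub <- dplyr::filter(rv, .data$field == fld)
    w <- pair_by_class(sub, "mean_gradient_ms_mm")
    try_test(sprintf("%s_gradient_aLGE_vs_healthy_all_cl", fld), fld,
             if (nrow(w) >= 2) paired_t(w$aLGE, w$healthy, exclude = exclude)
             else stop("fewer than 2 complete pairs"))
  }

  # RV vs LV within subjects (pig x cycle length units mapped from both)
  both <- dplyr::add_count(summaries, .data$pig, .data$cycle_length,
                           .data$tissue_class, .data$field, name = "n_ch")
  both <- dplyr::filter(both, .data$n_ch == 2)
  metrics <- c(mean = "mean_ms", heterogeneity = "sd_ms",
               gradient = "mean_gradient_ms_mm")
  for (fld in c("ari", "rt")) {
    use_metrics <- if (fld == "ari") metrics else metrics["gradient"]
    for (mi in seq_along(use_metrics)) {
      for (cls in c("aLGE", "healthy")) {
        sub <- dplyr::filter(both, .data$field == fld, .data$tissue_class == cls)
        sub$unit <- paste(sub$pig, sub$cycle_length, sep = "_")
        try_test(sprintf("%s_%s_RV_vs_LV_%s", fld, names(use_metrics)[mi], cls), fld,
                 if (length(unique(sub$unit)) >= 2) {
                   rm_anova(sub, use_metrics[[mi]], "pacing_chamber", "unit",
                            exclude = exclude)
                 } else stop("fewer than 2 subjects with both chambers"))
      }
    }
  }

  # pacing distance effects on aLGE gradients
  for (fld in c("ari", "rt")) {
    sub <- dplyr::filter(summaries, .data$field == fld,
                         .data$tissue_class == "aLGE")
    try_test(sprintf("%s_gradient_vs_pacing_distance", fld), fld,
             if (nrow(sub) >= 3) {
               pearson_with_t(sub$mean_gradient_ms_mm, sub$pacing_distance_mm,
                              exclude = exclude)
             } else stop("fewer than 3 cases"))
    try_test(sprintf("%s_gradient_pacing_le10_vs_gt10", fld), fld,
             if (length(unique(sub$pacing_class)) >= 2) {
               unbalanced_anova(sub$mean_gradient_ms_mm, sub$pacing_class,
                                exclude = exclude)
             } else stop("only one pacing-distance class present"))
  }

  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "comparison", "field")
}
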