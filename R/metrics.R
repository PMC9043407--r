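#' Tissue-stratified summaries of a per-site value
#'
#' Per class: site count, arithmetic mean, and heterogeneity as the
#' sample standard deviation (n - 1). Classes with fewer than two sites
#' are flagged `insufficient` rather than silently summarized.
#'
#' @param sites Data frame with one row per site.
#' @param value Column name (string) of the value to summarize.
#' @param class Column name of the tissue class (default
#'   `"tissue_class"`).
#' @return Tibble: class column, `n_sites`, `mean`, `sd`, `insufficient`.
#' @export
summarize_region <- function(sites, value, class = "tissue_class") {
  dplyr::summarise(
    dplyr::group_by(sites, dplyr::across(dplyr::all_of(class))),
    n_sites = dplyr::n(),
    mean = mean(.data[[value]]),
    sd = sd(.data[[value]]),
    insufficient = dplyr::n() < 2,
    .groups = "drop")
}

#' Per-class mean gradient
#'
#' [summarize_region()] applied to local gradient magnitudes (ms/mm).
#'
#' @inheritParams summarize_region
#' @param gradient Column name of the gradient magnitude.
#' @return Tibble as [summarize_region()].
#' @export
summarize_gradients <- function(sites, gradient = "gradient_ms_mm",
                                class = "tissue_class") {
  summarize_region(sites, gradient, class)
}

#' Full region summary for one analyzed case
#'
#' Builds the per-case, per-tissue-class rows that feed the study
#' statistics: mean and SD (heterogeneity) of the site-level field value,
#' and the mean local gradient, for both ARI and repolarization time.
#' Summaries use retained sites (post consistency filter and interface
#' exclusion); gradients come from the interpolated node field sampled at
#' each retained site's nearest node.
#'
#' @param sites Retained site table with columns `tissue_class`, `ari_ms`,
#'   `rt_ms`, `ari_gradient_ms_mm`, `rt_gradient_ms_mm`.
#' @param case_info One-row data frame (or list) with case metadata to
#'   replicate onto each row (e.g. `case_id`, `pig`, `pacing_chamber`,
#'   `cycle_length`, `pacing_distance_mm`, `pacing_class`).
#' @return Tibble, one row per tissue class x field (`field` in
#'   `"ari"`, `"rt"`), columns `n_sites`, `mean_ms`, `sd_ms`,
#'   `mean_gradient_ms_mm` plus the metadata.
#' @export
case_region_summary <- function(sites, case_info = NULL) {
  one_field <- function(fld) {
    v <- summarize_region(sites, paste0(fld, "_ms"))
    g <- summarize_gradients(sites, paste0(fld, "_gradient_ms_mm"))
    out <- dplyr::left_join(
      dplyr::rename(v, mean_ms = "mean", sd_ms = "sd"),
      dplyr::select(
        dplyr::rename(g, mean_gradient_ms_mm = "mean"),
        "tissue_class", "mean_gradient_ms_mm"),
      by = "tissue_class")
    out$field <- fld
    out
  }
  res <- dplyr::bind_rows(one_field("ari"), one_field("rt"))
  if (!is.null(case_info)) {
    res <- dplyr::bind_cols(tibble::as_tibble(case_info)[rep(1, nrow(res)), ], res)
  }
  dplyr::relocate(res, "field", .after = dplyr::last_col())
}
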