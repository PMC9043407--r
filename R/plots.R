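#' Plot one electrogram with its fiducials
#'
#' Unipolar trace with detected activation (circles) and repolarization
#' (squares) marked per beat.
#'
#' @param case A `map_case`.
#' @param site One `site_id` present in the case.
#' @param annotations Optional precomputed [egm_fiducials()] table;
#'   computed for the single site when absent.
#' @param config A [detector_config()].
#' @return A ggplot object.
#' @export
plot_electrogram <- function(case, site, annotations = NULL,
                             config = detector_config()) {
  i <- match(site, case$records$site_id)
  if (is.na(i)) abort(sprintf("site '%s' not found", site))
  r <- case$records[i, ]
  v <- r$unipolar[[1]]
  df <- tibble::tibble(t_ms = (seq_along(v) - 1) * 1000 / r$sampling_rate, mv = v)
  if (is.null(annotations)) {
    annotations <- annotate_beats(v, r$bipolar[[1]] %||% NULL,
                                  r$stimulus_times[[1]], r$sampling_rate,
                                  r$segment_ms, config)
    annotations$site_id <- site
  }
  ann <- dplyr::filter(annotations, .data$site_id == site, .data$valid)
  at_pts <- tibble::tibble(t_ms = ann$at_ms,
                           mv = v[round(ann$at_ms * r$sampling_rate / 1000) + 1])
  rt_pts <- tibble::tibble(t_ms = ann$rt_ms,
                           mv = v[round(ann$rt_ms * r$sampling_rate / 1000) + 1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = at_pts, color = "red", size = 2) +
    ggplot2::geom_point(data = rt_pts, color = "darkgreen", shape = 15, size = 2) +
    ggplot2::labs(x = "time (ms)", y = "unipolar (mV)",
                  title = sprintf("%s - %s", case$case_id, site)) +
    ggplot2::theme_minimal()
}

#' Map a node field on the shell
#'
#' Orthographic projection of the front-facing triangles, colored by the
#' mean node value — a quick 2-D rendering of ARI, gradient or label maps
#' (use [export_result_shell()] + a 3-D viewer for full inspection).
#'
#' @param shell An [new_shell()] object.
#' @param field Field name, or `"label"` for the tissue classes.
#' @param view_axis Projection axis: 1, 2 or 3 (x/y/z; default 3).
#' @return A ggplot object.
#' @export
plot_shell_field <- function(shell, field, view_axis = 3) {
  tr <- shell$triangles
  keep_ax <- setdiff(1:3, view_axis)
  p1 <- shell$coords[tr[, 1], , drop = FALSE]
  u <- shell$coords[tr[, 2], , drop = FALSE] - p1
  v <- shell$coords[tr[, 3], , drop = FALSE] - p1
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  ctr <- (p1 + shell$coords[tr[, 2], ] + shell$coords[tr[, 3], ]) / 3
  ctr <- sweep(ctr, 2, colMeans(shell$coords))
  front <- rowSums(nrm * ctr) > 0 & ctr[, view_axis] > 0
  tri_f <- tr[front, , drop = FALSE]
  if (field == "label") {
    val <- shell$node_data$label
    tri_val <- val[tri_f[, 1]]
  } else {
    val <- get_field(shell, field)
    tri_val <- (val[tri_f[, 1]] + val[tri_f[, 2]] + val[tri_f[, 3]]) / 3
  }
  poly <- tibble::tibble(
    id = rep(seq_len(nrow(tri_f)), each = 3),
    px = shell$coords[t(tri_f), keep_ax[1]],
    py = shell$coords[t(tri_f), keep_ax[2]],
    value = rep(tri_val, each = 3))
  p <- ggplot2::ggplot(poly, ggplot2::aes(x = .data$px, y = .data$py,
                                          group = .data$id, fill = .data$value)) +
    ggplot2::geom_polygon(color = NA) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mm", y = "mm", fill = field) +
    ggplot2::theme_minimal()
  if (field == "label") p else p + ggplot2::scale_fill_viridis_c()
}

#' @export
autoplot.ari_case_result <- function(object, field = "ari", ...) {
  plot_shell_field(object$shell, field)
}

#' Study-level summary plot
#'
#' Boxplots of the per-case region summaries by tissue class and cycle
#' length (mean ARI by default), mirroring the tissue-stratified
#' comparisons the statistics run on.
#'
#' @param object An `ari_study_result`.
#' @param metric Column of the summaries to show (default `"mean_ms"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ari_study_result <- function(object, metric = "mean_ms", ...) {
  df <- dplyr::filter(object$summaries, .data$field == "ari")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue_class,
                                   y = .data[[metric]],
                                   fill = .data$tissue_class)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, size = 1) +
    ggplot2::facet_wrap(~cycle_length, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
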