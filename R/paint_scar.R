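#' Paint a geodesic scar patch onto a shell
#'
#' Labels nodes by along-surface (graph-geodesic) distance from a center
#' node: closer than `radius_mm` becomes `"scar"`, within
#' `[radius_mm, radius_mm + bz_rim_mm)` becomes `"border_zone"`, the rest
#' `"healthy"`. This is a synthetic stand-in for imaging-derived tissue
#' classification.
#'
#' @param shell An [new_shell()] object.
#' @param center_node Node index of the scar center.
#' @param radius_mm Scar radius along the surface (> 0).
#' @param bz_rim_mm Width of the border-zone rim (>= 0).
#' @return The shell with `node_data$label` filled in.
#' @export
paint_scar <- function(shell, center_node, radius_mm, bz_rim_mm = 3) {
  n <- n_nodes(shell)
  if (length(center_node) != 1 || center_node < 1 || center_node > n) {
    abort(sprintf("`center_node` must be a node index in 1..%d", n))
  }
  if (radius_mm <= 0) abort("`radius_mm` must be > 0.")
  if (bz_rim_mm < 0) abort("`bz_rim_mm` must be >= 0.")
  d <- fmm_distance(shell, center_node)
  lab <- rep("healthy", n)
  lab[d < radius_mm + bz_rim_mm] <- "border_zone"
  lab[d < radius_mm] <- "scar"
  shell$node_data$label <- lab
  shell
}
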