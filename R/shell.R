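#' Triangulated endocardial shell
#'
#' An `ari_shell` bundles a triangulated surface (node coordinates in mm,
#' triangle connectivity) with per-node data: a tissue label
#' (`"healthy"`, `"border_zone"`, `"scar"`) and any number of named scalar
#' fields (ARI in ms, repolarization time in ms, gradients in ms/mm,
#' bipolar voltage in mV, scar-interface distance in mm, ...). Per-node data
#' live in a tibble (`$node_data`) so downstream code can use ordinary
#' dplyr verbs on it.
#'
#' @param coords Numeric matrix, one row per node, columns x/y/z in mm.
#' @param triangles Integer matrix, one row per triangle, 1-based node
#'   indices.
#' @param labels Optional character/factor vector of per-node tissue labels
#'   in `c("healthy", "border_zone", "scar")` (NA allowed).
#' @param fields Optional named list of per-node numeric vectors.
#'
#' @return An object of class `ari_shell` with elements `coords`,
#'   `triangles` and `node_data` (tibble with `node_id`, `label` and one
#'   column per field).
#' @export
new_shell <- function(coords, triangles, labels = NULL, fields = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3) abort("`coords` must have 3 columns (x, y, z in mm).")
  colnames(coords) <- c("x", "y", "z")
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3) abort("`triangles` must have 3 columns.")
  n <- nrow(coords)
  if (nrow(triangles) > 0 && (min(triangles) < 1 || max(triangles) > n)) {
    bad <- which(apply(triangles, 1, function(tr) any(tr < 1 | tr > n)))[1]
    abort(sprintf(
      "triangle %d references a node outside 1..%d", bad, n))
  }
  if (is.null(labels)) labels <- rep(NA_character_, n)
  labels <- as.character(labels)
  if (length(labels) != n) abort("`labels` must have one entry per node.")
  known <- c("healthy", "border_zone", "scar")
  if (any(!is.na(labels) & !labels %in% known)) {
    abort("labels must be one of 'healthy', 'border_zone', 'scar' (or NA).")
  }
  nd <- tibble::tibble(node_id = seq_len(n), label = labels)
  for (nm in names(fields)) {
    v <- as.numeric(fields[[nm]])
    if (length(v) != n) abort(sprintf("field '%s' must have one value per node.", nm))
    nd[[nm]] <- v
  }
  structure(
    list(coords = coords, triangles = triangles, node_data = nd),
    class = "ari_shell"
  )
}

#' @export
print.ari_shell <- function(x, ...) {
  flds <- setdiff(names(x$node_data), c("node_id", "label"))
  cat(sprintf("<ari_shell> %d nodes, %d triangles\n",
              nrow(x$coords), nrow(x$triangles)))
  if (any(!is.na(x$node_data$label))) {
    tab <- table(x$node_data$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (length(flds)) cat("  fields:", paste(flds, collapse = ", "), "\n")
  invisible(x)
}

n_nodes <- function(shell) nrow(shell$coords)

#' Per-node scalar fields on a shell
#'
#' `set_field()` attaches (or replaces) a named per-node scalar field;
#' `get_field()` retrieves one, erroring with the list of available fields
#' when the name is unknown.
#'
#' @param shell An [new_shell()] object.
#' @param name Field name.
#' @param values Numeric vector, one value per node.
#' @return `set_field()` the modified shell; `get_field()` a numeric vector.
#' @export
set_field <- function(shell, name, values) {
  values <- as.numeric(values)
  if (length(values) != n_nodes(shell)) {
    abort(sprintf("field '%s' must have %d values.", name, n_nodes(shell)))
  }
  shell$node_data[[name]] <- values
  shell
}

#' @rdname set_field
#' @export
get_field <- function(shell, name) {
  flds <- setdiff(names(shell$node_data), c("node_id", "label"))
  if (!name %in% flds) {
    abort(sprintf("unknown field '%s'; available: %s", name,
                  if (length(flds)) paste(flds, collapse = ", ") else "(none)"))
  }
  shell$node_data[[name]]
}

#' Unique mesh edges with lengths
#'
#' @param shell An [new_shell()] object.
#' @return Tibble with `from`, `to` (1-based node ids, from < to) and
#'   `length` (mm).
#' @export
shell_edges <- function(shell) {
  tr <- shell$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated((e[, 1] - 1) * n_nodes(shell) + e[, 2]), , drop = FALSE]
  d <- shell$coords[e[, 1], , drop = FALSE] - shell$coords[e[, 2], , drop = FALSE]
  tibble::new_tibble(list(from = e[, 1], to = e[, 2],
                          length = sqrt(rowSums(d^2))), nrow = nrow(e))
}

#' Triangle areas (mm^2)
#' @param shell An [new_shell()] object.
#' @return Numeric vector, one area per triangle.
#' @export
triangle_areas <- function(shell) {
  tr <- shell$triangles
  p1 <- shell$coords[tr[, 1], , drop = FALSE]
  u <- shell$coords[tr[, 2], , drop = FALSE] - p1
  v <- shell$coords[tr[, 3], , drop = FALSE] - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Euler characteristic V - E + F
#' @param shell An [new_shell()] object.
#' @return Integer; 2 for a closed sphere-topology mesh.
#' @export
euler_characteristic <- function(shell) {
  n_nodes(shell) - nrow(shell_edges(shell)) + nrow(shell$triangles)
}

# Weighted igraph of the mesh. With shortcuts = TRUE, every interior edge
# contributes an extra edge between the two opposite triangle apexes, with
# the hinge-unfolded in-plane length (only when the unfolded segment
# actually crosses the shared edge); this tightens graph-geodesic
# distances on curved surfaces.
shell_graph <- function(shell, shortcuts = TRUE) {
  ed <- shell_edges(shell)
  from <- ed$from; to <- ed$to; w <- ed$length
  if (shortcuts && nrow(shell$triangles) > 1) {
    sc <- unfolded_shortcuts(shell)
    if (nrow(sc)) {
      from <- c(from, sc$from); to <- c(to, sc$to); w <- c(w, sc$length)
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = n_nodes(shell), directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

# Hinge-unfold every pair of triangles sharing an edge; returns apex-apex
# segments that cross the shared edge, with their flattened lengths.
unfolded_shortcuts <- function(shell) {
  tr <- shell$triangles
  nn <- n_nodes(shell)
  key <- function(x, y) (pmin(x, y) - 1) * nn + pmax(x, y)
  ek <- c(key(tr[, 1], tr[, 2]), key(tr[, 2], tr[, 3]), key(tr[, 1], tr[, 3]))
  opp <- c(tr[, 3], tr[, 1], tr[, 2])
  o <- order(ek)
  eks <- ek[o]; opps <- opp[o]
  m <- length(eks)
  pair <- which(eks[-m] == eks[-1])   # interior edges appear exactly twice
  if (!length(pair)) {
    return(tibble::tibble(from = integer(), to = integer(), length = double()))
  }
  kk <- eks[pair]
  a <- as.integer((kk - 1) %/% nn + 1)
  b <- as.integer((kk - 1) %% nn + 1)
  cc <- opps[pair]; dd <- opps[pair + 1]
  P <- shell$coords
  eab <- P[b, , drop = FALSE] - P[a, , drop = FALSE]
  lab <- sqrt(rowSums(eab^2))
  u <- eab / lab
  # planar coordinates of each apex in the frame of edge (a,b)
  plan <- function(apex) {
    v <- P[apex, , drop = FALSE] - P[a, , drop = FALSE]
    xx <- rowSums(v * u)
    yy <- sqrt(pmax(rowSums(v^2) - xx^2, 0))
    cbind(xx, yy)
  }
  c2 <- plan(cc); d2 <- plan(dd)
  d2[, 2] <- -d2[, 2]  # unfold to opposite sides of the shared edge
  # intersection of segment c2-d2 with the x axis
  dy <- c2[, 2] - d2[, 2]
  tpar <- ifelse(dy > 0, c2[, 2] / dy, NA_real_)
  xint <- c2[, 1] + tpar * (d2[, 1] - c2[, 1])
  crosses <- !is.na(xint) & xint >= 0 & xint <= lab
  len <- sqrt(rowSums((c2 - d2)^2))
  tibble::tibble(from = cc[crosses], to = dd[crosses], length = len[crosses])
}

# Index of the shell node nearest each query point (rows of `pts`).
nearest_node <- function(shell, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  P <- shell$coords
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (P[, 1] - pts[i, 1])^2 + (P[, 2] - pts[i, 2])^2 + (P[, 3] - pts[i, 3])^2
    which.min(d2)
  }, integer(1))
}

# aLGE = scar + border zone merged; returns "aLGE"/"healthy"/NA per node.
merged_labels <- function(labels) {
  out <- rep(NA_character_, length(labels))
  out[labels %in% c("scar", "border_zone")] <- "aLGE"
  out[labels %in% "healthy"] <- "healthy"
  out
}
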