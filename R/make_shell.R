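#' Generate a synthetic triangulated shell
#'
#' Builds a closed sphere or ellipsoid, or an open ventricle-like cap, by
#' recursive icosahedron subdivision. Subdivision yields node counts
#' 12, 42, 162, 642, 2562, 10242, ...; the smallest count at or above
#' `n_nodes` is used (the actual count is `nrow(shell$coords)`). Edge
#' lengths are approximately uniform. The seed fixes a random rigid
#' rotation so that different seeds give different node placements on the
#' same surface; the mesh is fully deterministic given the seed.
#'
#' @param kind `"sphere"`, `"ellipsoid"` or `"ventricle_cap"` (an open cap
#'   covering roughly the lower 80 percent of a sphere, emulating an
#'   LV endocardial shell with the base open at the valve plane).
#' @param n_nodes Minimum number of nodes (>= 4).
#' @param radius Sphere radius in mm (default 25, an adult LV-scale
#'   chamber); for `"ellipsoid"` a length-3 vector of semi-axes.
#' @param seed Integer seed for the rotation.
#' @return An [new_shell()] object.
#' @examples
#' sh <- make_shell("sphere", 162, radius = 25, seed = 1)
#' range(sqrt(rowSums(sh$coords^2)))  # all 25
#' @export
make_shell <- function(kind = c("sphere", "ellipsoid", "ventricle_cap"),
                       n_nodes, radius = 25, seed = 1) {
  kind <- match.arg(kind)
  if (n_nodes < 4) abort("`n_nodes` must be at least 4.")
  counts <- 10 * 4^(0:7) + 2
  lev <- match(TRUE, counts >= if (kind == "ventricle_cap") ceiling(n_nodes / 0.8) else n_nodes)
  if (is.na(lev)) abort("`n_nodes` too large (max subdivision 7).")
  ico <- icosphere(lev - 1)
  rot <- rotation_from_seed(seed)
  V <- ico$coords %*% t(rot)
  if (kind == "ellipsoid") {
    ax <- if (length(radius) == 3) radius else radius * c(1, 0.8, 1.4)
    V <- sweep(V, 2, ax, "*")
  } else {
    V <- V * radius[1]
  }
  if (kind == "ventricle_cap") {
    # open the mesh at the top: drop triangles with any node above the cut
    zcut <- quantile(V[, 3], 0.8, names = FALSE)
    keep_node <- V[, 3] <= zcut
    keep_tri <- keep_node[ico$triangles[, 1]] &
      keep_node[ico$triangles[, 2]] & keep_node[ico$triangles[, 3]]
    tri <- ico$triangles[keep_tri, , drop = FALSE]
    used <- sort(unique(as.vector(tri)))
    remap <- integer(nrow(V)); remap[used] <- seq_along(used)
    return(new_shell(V[used, , drop = FALSE],
                     matrix(remap[tri], ncol = 3)))
  }
  new_shell(V, ico$triangles)
}

# Unit icosphere: `level` recursive 1->4 triangle subdivisions of an
# icosahedron, midpoints projected to the unit sphere.
icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  tri <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(level)) {
    n <- nrow(V)
    ek <- function(a, b) (pmin(a, b) - 1) * n + pmax(a, b)
    e12 <- ek(tri[, 1], tri[, 2]); e23 <- ek(tri[, 2], tri[, 3])
    e13 <- ek(tri[, 1], tri[, 3])
    keys <- unique(c(e12, e23, e13))
    a <- (keys - 1) %/% n + 1; b <- (keys - 1) %% n + 1
    mid <- (V[a, , drop = FALSE] + V[b, , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    idx <- setNames(n + seq_along(keys), keys)
    m12 <- idx[as.character(e12)]; m23 <- idx[as.character(e23)]
    m13 <- idx[as.character(e13)]
    V <- rbind(V, mid)
    tri <- rbind(
      cbind(tri[, 1], m12, m13),
      cbind(tri[, 2], m23, m12),
      cbind(tri[, 3], m13, m23),
      cbind(m12, m23, m13))
  }
  dimnames(tri) <- NULL
  list(coords = V, triangles = matrix(as.integer(tri), ncol = 3))
}

# Deterministic random rotation matrix from an integer seed.
rotation_from_seed <- function(seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
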