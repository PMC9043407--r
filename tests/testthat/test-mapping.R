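test_that("Shepard interpolation honors exact hits, constants, and the weight formula", {
  sites <- tibble::tibble(x = c(0, 10), y = 0, z = 0, value = c(10, 20))
  q <- new_shell(rbind(c(5, 0, 0), c(0, 0, 0), c(2, 0, 0)),
                 matrix(c(1L, 2L, 3L), 1))
  v <- shepard_interpolate(sites, q)
  # midpoint, power 2: w1 = w2 -> (10 + 20) / 2
  expect_equal(v[1], 15, tolerance = 1e-12)
  expect_identical(v[2], 10)  # coincident node takes the site value
  # hand evaluation at x = 2: w1 = 1/4, w2 = 1/64
  expect_equal(v[3], (10 / 4 + 20 / 64) / (1 / 4 + 1 / 64), tolerance = 1e-12)
  one <- shepard_interpolate(sites[1, ], q)
  expect_equal(one, rep(10, 3))
  expect_error(shepard_interpolate(sites[0, ], q), "at least one site")
})

test_that("Shepard output is bounded by the site values on random configurations", {
  set.seed(41)
  for (i in 1:100) {
    sh <- grid_shell(6, 6, jitter = 0.3, seed = i)
    ns <- sample(2:15, 1)
    sites <- tibble::tibble(x = runif(ns, 0, 5), y = runif(ns, 0, 5),
                            z = 0, value = rnorm(ns, 300, 30))
    v <- shepard_interpolate(sites, sh)
    expect_true(all(v >= min(sites$value) - 1e-9 & v <= max(sites$value) + 1e-9))
    const <- shepard_interpolate(dplyr::mutate(sites, value = 42), sh)
    expect_equal(const, rep(42, 36), tolerance = 1e-9)
  }
})

test_that("tag transfer equals brute-force nearest-neighbor assignment", {
  src_sh <- make_shell("sphere", 162, radius = 25, seed = 6)
  src_sh <- paint_scar(src_sh, 10, 15, bz_rim_mm = 4)
  # identical geometry: labels copied exactly
  tgt_same <- new_shell(src_sh$coords, src_sh$triangles)
  expect_identical(transfer_tags(src_sh, tgt_same)$node_data$label,
                   src_sh$node_data$label)
  # distinct target: brute-force oracle
  tgt <- make_shell("sphere", 42, radius = 25, seed = 99)
  got <- transfer_tags(src_sh, tgt)$node_data$label
  oracle <- character(42)
  for (i in 1:42) {
    d2 <- colSums((t(src_sh$coords) - tgt$coords[i, ])^2)
    oracle[i] <- src_sh$node_data$label[which.min(d2)]
  }
  expect_identical(got, oracle)
  # single-label source paints everything
  uni <- tibble::tibble(x = 0, y = 0, z = 0, label = "scar")
  expect_true(all(transfer_tags(uni, tgt)$node_data$label == "scar"))
  expect_error(transfer_tags(dplyr::mutate(uni, label = NA_character_), tgt),
               "labeled")
})

test_that("interface distance is zero on interface nodes and metric on a strip", {
  sh <- grid_shell(30, 8)
  sh$node_data$label <- ifelse(sh$coords[, 1] <= 9, "scar", "healthy")
  sh <- scar_interface_distance(sh)
  d <- get_field(sh, "scar_distance")
  x <- sh$coords[, 1]
  iface <- (x == 9) | (x == 10)
  expect_true(all(d[iface] == 0))
  oracle <- ifelse(x <= 9, 9 - x, x - 10)
  sel <- oracle > 0
  expect_lt(max(abs(d[sel] - oracle[sel]) / oracle[sel]), 0.02)
  # signed variant is negative inside aLGE
  shs <- scar_interface_distance(sh, signed = TRUE)
  ds <- get_field(shs, "scar_distance")
  expect_true(all(ds[x < 9] < 0) && all(ds[x > 10] > 0))
})

test_that("single-class shells warn and return infinite distances", {
  sh <- grid_shell(4, 4)
  sh$node_data$label <- "healthy"
  expect_warning(sh <- scar_interface_distance(sh), "single")
  expect_true(all(is.infinite(get_field(sh, "scar_distance"))))
})

test_that("interface exclusion removes exactly the |distance| <= band sites", {
  sh <- grid_shell(30, 8)
  sh$node_data$label <- ifelse(sh$coords[, 1] <= 9, "scar", "healthy")
  sh <- scar_interface_distance(sh, signed = TRUE)
  sites <- tibble::tibble(x = runif(200, 0, 29), y = runif(200, 0, 7), z = 0)
  kept2 <- exclude_near_interface(sites, sh, band = 2)
  expect_true(all(abs(kept2$scar_distance_mm) > 2))
  expect_true(all(kept2$tissue_class %in% c("aLGE", "healthy")))
  kept0 <- exclude_near_interface(sites, sh, band = 0)
  counts <- vapply(c(0, 1, 2, 4), function(b)
    nrow(exclude_near_interface(sites, sh, band = b)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gte(nrow(kept0), nrow(kept2))
})

test_that("gradients vanish on constant fields and are exact for affine fields", {
  sh <- grid_shell(12, 10, jitter = 0.3, seed = 3)
  n <- nrow(sh$coords)
  for (mode in c("edge", "edge_mean", "element")) {
    expect_equal(local_gradient(sh, rep(7, n), mode), rep(0, n))
  }
  f <- 3 * sh$coords[, 1] - 2 * sh$coords[, 2]
  tru <- sqrt(13)
  expect_lt(max(abs(local_gradient(sh, f, "element") - tru)), 1e-9)
  expect_lt(max(abs(local_gradient(sh, f, "edge") - tru)), 1e-9)
})

test_that("edge_mean gradient equals the hand-computed mean of |df|/len on a fan", {
  # equilateral-ish fan: center node 1 connected to a ring
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  coords <- rbind(c(0, 0, 0), cbind(cos(ang), sin(ang), 0))
  tri <- cbind(1, 2:7, c(3:7, 2))
  sh <- new_shell(coords, tri)
  vals <- c(5, 1, 2, 3, 4, 5, 6)
  g <- local_gradient(sh, vals, "edge_mean")
  ring_pairs <- cbind(2:7, c(3:7, 2))
  ring_len <- sqrt(rowSums((coords[ring_pairs[, 1], ] - coords[ring_pairs[, 2], ])^2))
  expect_equal(g[1], mean(abs(vals[2:7] - 5)))
  expect_equal(g[2], mean(c(abs(vals[2] - 5) / 1,
                            abs(vals[2] - vals[3]) / ring_len[1],
                            abs(vals[2] - vals[7]) / ring_len[6])))
})

test_that("pacing distance classification uses the inclusive 10 mm cut", {
  sh <- grid_shell(30, 8)
  sh$node_data$label <- ifelse(sh$coords[, 1] <= 9, "scar", "healthy")
  sh <- scar_interface_distance(sh, signed = TRUE)
  at_iface <- pacing_distance_to_scar(c(10, 3, 0), sh)
  expect_equal(at_iface$pacing_distance_mm, 0)
  expect_identical(at_iface$pacing_class, "<=10mm")
  at_20 <- pacing_distance_to_scar(c(29, 3, 0), sh)   # 19 mm from x = 10 line
  expect_identical(at_20$pacing_class, ">10mm")
  expect_equal(at_20$pacing_distance_mm, 19)
  exact10 <- pacing_distance_to_scar(c(20, 3, 0), sh) # exactly 10 mm
  expect_identical(exact10$pacing_class, "<=10mm")
})
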