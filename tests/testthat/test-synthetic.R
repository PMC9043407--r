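test_that("scar painting follows geodesic radius and area fraction", {
  sh <- make_shell("sphere", 2562, radius = 1, seed = 4)
  expect_error(paint_scar(sh, 9999, 0.5), "node index")
  fr <- vapply(c(0.3, 0.6, 0.9), function(r) {
    s <- paint_scar(sh, 1, r, bz_rim_mm = 0)
    mean(s$node_data$label == "scar")
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  # spherical-cap area fraction oracle: fraction = (1 - cos(theta)) / 2
  s <- paint_scar(sh, 1, 0.8, bz_rim_mm = 0)
  areas <- triangle_areas(s)
  lab <- s$node_data$label
  tri_scar <- rowMeans(matrix(lab[s$triangles] == "scar", ncol = 3))
  frac <- sum(areas * tri_scar) / sum(areas)
  expect_lt(abs(frac - (1 - cos(0.8)) / 2) / ((1 - cos(0.8)) / 2), 0.03)
})

test_that("synthetic electrograms place analytic fiducials exactly", {
  tru <- beat_truth(at = 100, ari = 300, polarity = "positive")
  v <- synth_electrogram(tru, stimulus_times = 0, noise_sd = 0, t_sigma = 25)
  vf <- lowpass(v, 1000, 80)
  d <- diff(vf)
  # steepest QRS downslope at AT = 100 ms
  expect_equal(which.min(d[1:250]), 101, tolerance = 1)
  # T peak at rt + sigma, maximal upslope before it at rt = 400 ms
  twin <- 250:500
  expect_lt(abs(twin[which.max(d[twin])] - 400), 1.5)
  vneg <- synth_electrogram(beat_truth(100, 300, "negative"), 0, t_sigma = 25)
  vnf <- lowpass(vneg, 1000, 80)
  trough <- 250 + which.min(vnf[250:500]) - 1
  expect_equal(trough, 376, tolerance = 1.5)     # trough at rt - sigma
  post <- trough:600
  expect_lt(abs(post[which.max(diff(vnf)[post])] - 400), 1.5)
  expect_error(
    synth_electrogram(beat_truth(600, 380, "positive"), 0, t_sigma = 25),
    "infeasible")
})

test_that("cases contain 2 analyzable complexes at 500 ms pacing and 3 at 300 ms", {
  for (spec in list(c(500, 2), c(300, 3))) {
    mc <- small_case(cycle_length = spec[1])
    expect_true(all(vapply(mc$case$records$stimulus_times,
                           function(s) all(diff(s) == spec[1]), logical(1))))
    expect_equal(max(mc$truth$beat), spec[2])
  }
  expect_silent(validate_case(small_case()$case))
})

test_that("true ARI field reproduces the configured tissue offset", {
  # the spatial field is correlated, so the class-mean contrast is
  # assessed across seeds rather than with a naive per-site SE
  contrast <- function(seed, offset) {
    cfg <- synthetic_config(sites_per_case = 60, shell_nodes = 162,
                            rng_seed = seed, noise_sd = 0,
                            ari_offset_alge = offset)
    mc <- make_case(cfg, pig = 1, cycle_length = 500)
    lab <- ifelse(mc$case$shell$node_data$label == "healthy", "healthy", "aLGE")
    tr <- mc$truth[!duplicated(mc$truth$site_id), ]
    g <- split(tr$ari_ms, lab[tr$node_id])
    mean(g$aLGE) - mean(g$healthy)
  }
  d0 <- vapply(1:10, contrast, numeric(1), offset = 0)
  expect_lt(abs(mean(d0)), 2 * sd(d0) / sqrt(10) + 0.5)
  d20 <- vapply(11:20, contrast, numeric(1), offset = 20)
  expect_lt(abs(mean(d20) - 20), 2 * sd(d20) / sqrt(10) + 0.5)
})

test_that("generation is bit-deterministic given the config", {
  cfg <- synthetic_config(sites_per_case = 20, shell_nodes = 42, rng_seed = 5)
  a <- make_case(cfg, 1, 500)
  b <- make_case(cfg, 1, 500)
  expect_identical(a$case$records$unipolar, b$case$records$unipolar)
  expect_identical(a$truth, b$truth)
})

test_that("the spatial perturbation is zero-mean across seeds", {
  means <- vapply(1:10, function(s) {
    cfg <- synthetic_config(sites_per_case = 40, shell_nodes = 162,
                            rng_seed = s, noise_sd = 0)
    mc <- make_case(cfg, 1, 500)
    tr <- mc$truth[!duplicated(mc$truth$site_id), ]
    lab <- mc$case$shell$node_data$label[tr$node_id]
    mean(tr$ari_ms[lab == "healthy"]) - 300
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.5 + 2 * sd(means) / sqrt(10))
})

test_that("noise-free detection closes the loop on generated truth", {
  for (cl in c(500, 300)) {
    mc <- small_case(noise_sd = 0, cycle_length = cl, seed = 7)
    ann <- egm_fiducials(mc$case)
    j <- dplyr::inner_join(ann, mc$truth, by = c("site_id", "beat"),
                           suffix = c("", ".true"))
    j <- j[j$valid, ]
    expect_gt(nrow(j), 50)
    expect_lt(max(abs(j$at_ms - j$at_ms.true)), 1 + 1e-9)
    expect_lt(max(abs(j$rt_ms - j$rt_ms.true)), 1 + 1e-9)
    expect_lt(max(abs(j$ari_ms - j$ari_ms.true)), 2 + 1e-9)
    expect_identical(j$polarity, j$polarity.true)
  }
})

test_that("detection stays accurate at moderate trace noise", {
  mc <- small_case(noise_sd = 0.05, seed = 19, sites = 100)
  ann <- egm_fiducials(mc$case)
  j <- dplyr::inner_join(ann, mc$truth, by = c("site_id", "beat"),
                         suffix = c("", ".true"))
  j <- j[j$valid, ]
  expect_lte(median(abs(j$rt_ms - j$rt_ms.true)), 3)
  expect_lte(median(abs(j$at_ms - j$at_ms.true)), 1)
})
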