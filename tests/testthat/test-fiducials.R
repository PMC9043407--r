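test_that("the low-pass filter is zero-phase with unit DC gain", {
  x <- rep(3.7, 1000)
  expect_lt(max(abs(lowpass(x, 1000, 80) - 3.7)), 1e-9)
  t <- 0:999
  pass <- sin(2 * pi * 10 * t / 1000)
  expect_lt(abs(sqrt(mean(lowpass(pass, 1000, 80)^2)) / sqrt(mean(pass^2)) - 1), 0.02)
  stopb <- sin(2 * pi * 200 * t / 1000)
  expect_lt(sqrt(mean(lowpass(stopb, 1000, 80)^2)) / sqrt(mean(stopb^2)), 0.05)
  expect_error(lowpass(x, 1000, 600), "Nyquist")
})

test_that("bipolar construction is elementwise subtraction", {
  a <- rnorm(100)
  expect_equal(make_bipolar(a, a), rep(0, 100))
  expect_equal(make_bipolar(a + 2.5, a), rep(2.5, 100))
  b <- rnorm(100)
  oracle <- vapply(seq_along(a), function(i) a[i] - b[i], numeric(1))
  expect_identical(make_bipolar(a, b), oracle)
  expect_error(make_bipolar(a, b[-1]), "length")
})

test_that("beat segmentation yields 2 analyzable beats at 500 ms, 3 at 300 ms", {
  b500 <- segment_beats(c(0, 500), 1000)
  expect_identical(sum(b500$analyzable), 2L)
  b300 <- segment_beats(c(0, 300, 600, 900), 1000)
  expect_identical(sum(b300$analyzable), 3L)
  expect_false(b300$analyzable[4])
  expect_warning(late <- segment_beats(990, 1000), "analyzable")
  expect_identical(sum(late$analyzable), 0L)
  expect_error(segment_beats(numeric(0), 1000), "stimulus")
})

test_that("activation detection equals the exhaustive derivative argmin", {
  t <- 0:999
  v <- -2 / (1 + exp(-(t - 100) / 1.25))
  vf <- lowpass(v, 1000, 80)
  act <- detect_activation(vf, NULL, c(0, 150), 1000)
  expect_true(act$valid)
  expect_equal(act$at_ms, 100)
  # exhaustive oracle on random smooth traces
  set.seed(21)
  for (i in 1:25) {
    x <- lowpass(cumsum(rnorm(1000)), 1000, 40)
    w0 <- sample(100:700, 1); w1 <- w0 + sample(80:200, 1)
    got <- detect_activation(x, NULL, c(w0, w1), 1000)
    d <- numeric(1000)
    d[2:999] <- (x[3:1000] - x[1:998]) / 2
    d[1] <- x[2] - x[1]; d[1000] <- x[1000] - x[999]
    idx <- (w0 + 1):(w1 + 1)
    best <- idx[1]
    for (k in idx) if (d[k] < d[best]) best <- k
    expect_equal(got$at_ms, best - 1)
  }
  flat <- detect_activation(rep(0.2, 1000), NULL, c(0, 150), 1000)
  expect_false(flat$valid)
  expect_identical(flat$reason, "flat")
})

test_that("low-amplitude bipolar signals invalidate the beat", {
  t <- 0:999
  v <- -2 / (1 + exp(-(t - 100) / 1.25))
  vf <- lowpass(v, 1000, 80)
  act <- detect_activation(vf, rep(0.01, 1000), c(0, 150), 1000)
  expect_false(act$valid)
  expect_identical(act$reason, "no_deflection")
})

test_that("Wyatt detection matches the analytic Gaussian fiducials", {
  t <- 0:999
  base <- -2 / (1 + exp(-(t - 100) / 1.25))
  pos <- base + 0.5 * exp(-((t - 425)^2) / (2 * 25^2))
  rp <- detect_repolarization(lowpass(pos, 1000, 80), 100, 1000, 1000)
  expect_identical(rp$polarity, "positive")
  expect_lte(abs(rp$rt_ms - 400), 1)
  neg <- base - 0.5 * exp(-((t - 375)^2) / (2 * 25^2))
  rn <- detect_repolarization(lowpass(neg, 1000, 80), 100, 1000, 1000)
  expect_identical(rn$polarity, "negative")
  expect_lte(abs(rn$rt_ms - 400), 1)
})

test_that("Wyatt detection recovers randomized noise-free beats within a sample", {
  set.seed(31)
  cfg <- detector_config(qrs_window = 220)  # covers the randomized AT range
  for (i in 1:60) {
    at <- runif(1, 50, 200)
    ari <- runif(1, 150, 350)
    pol <- sample(c("positive", "negative"), 1)
    v <- synth_electrogram(beat_truth(at, ari, pol), 0, noise_sd = 0)
    ann <- annotate_beats(v, NULL, 0, 1000, 1000, cfg)
    expect_true(ann$valid[1])
    expect_lte(abs(ann$at_ms[1] - at), 1)
    expect_lte(abs(ann$rt_ms[1] - (at + ari)), 1)
    expect_identical(ann$polarity[1], pol)
  }
})

test_that("short T windows invalidate the beat", {
  t <- 0:999
  v <- -2 / (1 + exp(-(t - 100) / 1.25))
  rp <- detect_repolarization(lowpass(v, 1000, 80), 100, 230, 1000)
  expect_false(rp$valid)
  expect_identical(rp$reason, "t_window")
})

test_that("the 10% beat-consistency filter is strict and monotone", {
  ann_for <- function(ari1, ari2) {
    tibble::tibble(site_id = "s1", beat = 1:2, at_ms = c(100, 600),
                   rt_ms = c(100 + ari1, 600 + ari2),
                   ari_ms = c(ari1, ari2),
                   polarity = "positive", valid = TRUE, reason = "ok")
  }
  expect_false(consistency_filter(ann_for(300, 331))$kept)  # 10.33% > 10%
  expect_true(consistency_filter(ann_for(300, 330))$kept)   # exactly 10%
  # threshold monotonicity on a grid of beat pairs
  grid <- expand.grid(a1 = seq(100, 400, 50), ratio = seq(0.85, 1.15, 0.01))
  for (i in seq_len(nrow(grid))) {
    a1 <- grid$a1[i]; a2 <- grid$a1[i] * grid$ratio[i]
    k10 <- consistency_filter(ann_for(a1, a2), 0.10)$kept
    k05 <- consistency_filter(ann_for(a1, a2), 0.05)$kept
    expect_identical(k10, abs(a2 - a1) / a1 <= 0.10)
    expect_false(k05 && !k10)  # lowering the threshold never un-drops
  }
  one_beat <- ann_for(300, 300)[1, ]
  expect_false(consistency_filter(one_beat)$kept)
  expect_warning(z <- consistency_filter(ann_for(0, 10)), "zero")
  expect_false(z$kept)
})

test_that("ARI is invariant to a constant trace offset", {
  mc <- small_case(noise_sd = 0)
  r <- mc$case$records[3, ]
  a1 <- annotate_beats(r$unipolar[[1]], r$bipolar[[1]], r$stimulus_times[[1]])
  a2 <- annotate_beats(r$unipolar[[1]] + 7.3, r$bipolar[[1]], r$stimulus_times[[1]])
  expect_equal(a1$ari_ms, a2$ari_ms)
})

test_that("beat selection picks first, second, or mean ARI per site", {
  ann <- tibble::tibble(site_id = "s1", beat = 1:2, at_ms = c(100, 600),
                        rt_ms = c(400, 906), ari_ms = c(300, 306),
                        polarity = "positive", valid = TRUE, reason = "ok")
  expect_equal(site_ari(ann, detector_config(beat_select = "first"))$ari_ms, 300)
  expect_equal(site_ari(ann, detector_config(beat_select = "second"))$ari_ms, 306)
  expect_equal(site_ari(ann, detector_config(beat_select = "mean"))$ari_ms, 303)
})

test_that("first- and second-beat ARIs agree closely on filtered synthetic data", {
  mc <- small_case(noise_sd = 0.02, sites = 100, seed = 77)
  ann <- egm_fiducials(mc$case)
  keep <- consistency_filter(ann)
  kept <- ann[ann$valid & ann$site_id %in% keep$site_id[keep$kept] & ann$beat <= 2, ]
  w <- tidyr::pivot_wider(kept[, c("site_id", "beat", "ari_ms")],
                          names_from = "beat", values_from = "ari_ms")
  rel <- mean(abs(w$`1` - w$`2`)) / mean(w$`1`)
  expect_lt(rel, 0.02)
})
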