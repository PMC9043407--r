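# Structured triangulated planar grid in the xy plane (z = 0), optionally
# jittered, used as an analytic test surface.
grid_shell <- function(nx, ny, h = 1, jitter = 0, seed = 1) {
  xy <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1)) * h
  if (jitter > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    xy$x <- xy$x + runif(nrow(xy), -jitter, jitter)
    xy$y <- xy$y + runif(nrow(xy), -jitter, jitter)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  id <- function(i, j) (j - 1) * nx + i
  tris <- vector("list", 2 * (nx - 1) * (ny - 1))
  k <- 0
  for (j in 1:(ny - 1)) {
    for (i in 1:(nx - 1)) {
      tris[[k + 1]] <- c(id(i, j), id(i + 1, j), id(i, j + 1))
      tris[[k + 2]] <- c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
      k <- k + 2
    }
  }
  new_shell(cbind(as.matrix(xy), 0), do.call(rbind, tris))
}

# One-row-per-beat truth table for a single synthetic site.
beat_truth <- function(at, ari, polarity, beats = seq_along(at)) {
  tibble::tibble(beat = beats, at_ms = at, rt_ms = at + ari,
                 ari_ms = ari, polarity = polarity)
}

# Small standard case used by several tests (cached per session).
small_case <- local({
  cache <- new.env()
  function(noise_sd = 0.02, cycle_length = 500, seed = 42, sites = 60,
           nodes = 162, offset = 0) {
    key <- paste(noise_sd, cycle_length, seed, sites, nodes, offset, sep = "_")
    if (is.null(cache[[key]])) {
      cfg <- synthetic_config(sites_per_case = sites, shell_nodes = nodes,
                              rng_seed = seed, noise_sd = noise_sd,
                              ari_offset_alge = offset)
      cache[[key]] <- make_case(cfg, pig = 1, cycle_length = cycle_length)
    }
    cache[[key]]
  }
})

# One replicate of the six-pig tissue-contrast study: generates the study
# at the given master seed, runs the full per-case pipeline, and returns
# the paired-t estimate and p value for mean ARI in aLGE vs healthy
# (site-level percentile outlier exclusion applied inside run_case).
# Pigs whose map lacks a tissue class after filtering are dropped from
# the pairing.
study_tissue_t <- function(seed, offset, spatial_sd) {
  cfg <- synthetic_config(
    n_pigs = 6, lv_pigs = 0, sites_per_case = 60, shell_nodes = 642,
    cycle_lengths = 500, ari_offset_alge = offset,
    ari_spatial_sd = c("500" = spatial_sd, "300" = 15), rng_seed = seed)
  st <- make_study(cfg)
  pick <- function(s, cls) {
    v <- s$mean_ms[s$tissue_class == cls & s$field == "ari"]
    if (length(v) == 1) v else NA_real_
  }
  means <- t(vapply(st$cases, function(cs) {
    s <- run_case(cs)$summary
    c(pick(s, "aLGE"), pick(s, "healthy"))
  }, numeric(2)))
  ok <- stats::complete.cases(means)
  tt <- paired_t(means[ok, 1], means[ok, 2])
  c(est = tt$estimate, p = tt$p_value)
}
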