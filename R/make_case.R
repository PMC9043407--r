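#' Configuration for the synthetic study generator
#'
#' Defaults emulate the design of a six-pig chronic infarct mapping study:
#' ~4,296 sites per map with 19 percent of sites in imaging-defined scar
#' (aLGE = scar + border zone), pacing at 500 and 300 ms cycle lengths from
#' the RV in all pigs and additionally from the LV endocardium in four
#' pigs. Healthy-tissue mean ARIs default to 300 ms (500 ms pacing) and
#' 185 ms (300 ms pacing); spatial ARI heterogeneity defaults to 20 / 15 ms
#' SD. `ari_offset_alge` injects a known aLGE-vs-healthy ARI difference
#' (0 = null study).
#'
#' @param n_pigs Number of pigs (default 6).
#' @param lv_pigs How many of the pigs also receive LV endocardial pacing
#'   maps (default 4).
#' @param sites_per_case Mapping sites per case (default 4296). Sites are
#'   placed at mesh nodes, so the shell is refined until it has at least
#'   this many nodes.
#' @param scar_fraction Fraction of the surface in aLGE (default 0.19).
#' @param bz_rim_mm Border-zone rim width inside the aLGE patch, mm.
#' @param cycle_lengths Pacing cycle lengths, ms (default `c(500, 300)`).
#' @param shell_kind,shell_radius Passed to [make_shell()].
#' @param shell_nodes Minimum shell nodes; default grows with
#'   `sites_per_case`.
#' @param ari_mean_healthy Named vector of healthy mean ARI (ms) per cycle
#'   length.
#' @param ari_offset_alge Added to true ARI inside aLGE, ms.
#' @param ari_spatial_sd Named vector: SD (ms) of the spatially smooth
#'   ARI perturbation per cycle length.
#' @param ari_corr_length_mm Spatial correlation length of the ARI
#'   perturbation, mm. The node-wise white noise is diffused over the
#'   mesh graph for as many passes as this physical scale requires given
#'   the mesh edge length, so the field statistics are independent of
#'   mesh resolution.
#' @param t_polarity_neg Fraction of sites with negative T waves.
#' @param t_sigma Named vector of T-wave Gaussian SD (ms) per cycle length
#'   (narrower T at the short cycle length).
#' @param noise_sd Additive trace noise SD, mV.
#' @param conduction_velocity Apparent surface conduction velocity, mm/ms,
#'   used to derive activation latencies from the pacing site.
#' @param activation_delay_ms Fixed latency added at the pacing
#'   breakthrough, ms.
#' @param sampling_rate Hz. @param segment_ms Exported segment length, ms.
#' @param rng_seed Integer master seed; everything is deterministic given
#'   the config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pigs = 6, lv_pigs = 4,
                             sites_per_case = 4296,
                             scar_fraction = 0.19, bz_rim_mm = 3,
                             cycle_lengths = c(500, 300),
                             shell_kind = "sphere", shell_radius = 25,
                             shell_nodes = NULL,
                             ari_mean_healthy = c("500" = 300, "300" = 185),
                             ari_offset_alge = 0,
                             ari_spatial_sd = c("500" = 20, "300" = 15),
                             ari_corr_length_mm = 8,
                             t_polarity_neg = 0.3,
                             t_sigma = c("500" = 25, "300" = 10),
                             noise_sd = 0.02,
                             conduction_velocity = 5,
                             activation_delay_ms = 10,
                             sampling_rate = 1000, segment_ms = 1000,
                             rng_seed = 1) {
  if (scar_fraction < 0 || scar_fraction > 1) abort("scar_fraction must be in [0, 1].")
  if (noise_sd < 0) abort("noise_sd must be >= 0.")
  if (any(cycle_lengths <= 0) || sampling_rate <= 0 || segment_ms <= 0) {
    abort("durations and rates must be positive.")
  }
  if (is.null(shell_nodes)) shell_nodes <- max(sites_per_case, 162)
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

# Small deterministic per-case sub-seed (kept below 2^31).
case_seed <- function(rng_seed, pig, cycle_length, chamber) {
  (as.integer(rng_seed) * 1009L + pig * 131L + as.integer(cycle_length) +
     ifelse(chamber == "LV", 7L, 0L) * 17L) %% .Machine$integer.max
}

# Per-pig anatomy shared across that pig's maps: shell, scar labels,
# mapping-site nodes, unit-variance smooth perturbation, pacing nodes.
make_pig_anatomy <- function(config, pig) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(case_seed(config$rng_seed, pig, 1L, "RV"))
  shell <- make_shell(config$shell_kind, config$shell_nodes,
                      radius = config$shell_radius,
                      seed = config$rng_seed * 100 + pig)
  n <- n_nodes(shell)
  center <- sample.int(n, 1)
  # geodesic scar radius giving the requested aLGE area fraction on a
  # sphere: fraction = (1 - cos(theta)) / 2
  theta <- acos(1 - 2 * config$scar_fraction)
  r_alge <- config$shell_radius[1] * theta
  shell <- paint_scar(shell, center,
                      radius_mm = max(r_alge - config$bz_rim_mm, 1),
                      bz_rim_mm = config$bz_rim_mm)
  sites <- sort(sample.int(n, min(config$sites_per_case, n)))
  # diffusion passes such that the kernel scale ~ corr length:
  # k averaging passes spread noise over ~ sqrt(k/2) edge lengths
  mean_edge <- mean(shell_edges(shell)$length)
  passes <- min(2000L, max(1L, round(2 * (config$ari_corr_length_mm / mean_edge)^2)))
  f_unit <- smooth_unit_field(shell, passes)
  # pacing breakthrough nodes: RV septal-ish vs LV free-wall-ish, fixed
  # per pig but randomized across pigs
  pace <- sample.int(n, 2)
  polarity <- ifelse(runif(length(sites)) < config$t_polarity_neg,
                     "negative", "positive")
  list(shell = shell, sites = sites, f_unit = f_unit,
       pace_nodes = c(RV = pace[1], LV = pace[2]), polarity = polarity)
}

# Node-wise white noise diffused over the mesh graph, re-centered and
# rescaled to unit SD; clamped at +-2.5 so downstream truths stay feasible.
smooth_unit_field <- function(shell, passes) {
  n <- n_nodes(shell)
  ed <- shell_edges(shell)
  ctr <- c(ed$from, ed$to)
  oth <- c(ed$to, ed$from)
  deg <- tabulate(ctr, n)
  f <- rnorm(n)
  for (k in seq_len(passes)) {
    acc <- rowsum(f[oth], ctr, reorder = FALSE)
    nb <- numeric(n)
    nb[as.integer(rownames(acc))] <- acc
    f <- (f + nb / pmax(deg, 1)) / 2
  }
  f <- (f - mean(f)) / sd(f)
  f <- f - mean(f)
  pmin(pmax(f, -2.5), 2.5)
}

#' Generate one synthetic mapping case with ground truth
#'
#' Builds the shell, scar labels, mapping sites, pacing metadata and
#' per-site electrograms for one pig under one pacing protocol. The true
#' ARI field is `ari_mean_healthy + ari_offset_alge * [site in aLGE] +`
#' a spatially smooth zero-mean perturbation with SD `ari_spatial_sd`.
#' Activation latency grows with geodesic distance from the pacing node at
#' the configured conduction velocity; repolarization truth is
#' `AT + true ARI`. Everything is deterministic given the config.
#'
#' @param config A [synthetic_config()].
#' @param pig Pig index (1-based).
#' @param cycle_length Pacing cycle length, ms (one of
#'   `config$cycle_lengths`).
#' @param chamber `"RV"` or `"LV"`.
#' @param anatomy Optional pre-built per-pig anatomy (internal reuse across
#'   a pig's protocols).
#' @return List with `case` (a `map_case`) and `truth` (tibble: site_id,
#'   node_id, beat, at_ms, rt_ms, ari_ms, polarity).
#' @export
make_case <- function(config, pig = 1, cycle_length = 500, chamber = "RV",
                      anatomy = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(anatomy)) anatomy <- make_pig_anatomy(config, pig)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(case_seed(config$rng_seed, pig, cycle_length, chamber))

  shell <- anatomy$shell
  sites <- anatomy$sites
  cl <- as.character(cycle_length)
  mean_h <- unname(config$ari_mean_healthy[cl])
  sp_sd <- unname(config$ari_spatial_sd[cl])
  tsig <- unname(config$t_sigma[cl])
  if (is.na(mean_h) || is.na(sp_sd) || is.na(tsig)) {
    abort(sprintf("no generator constants for cycle length %s ms", cl))
  }

  lab <- merged_labels(shell$node_data$label)
  in_alge <- lab[sites] == "aLGE"
  ari_true <- mean_h + config$ari_offset_alge * in_alge +
    sp_sd * anatomy$f_unit[sites]

  pace_node <- anatomy$pace_nodes[[chamber]]
  gd <- fmm_distance(shell, pace_node)[sites]
  lat <- config$activation_delay_ms + gd / config$conduction_velocity

  stim <- seq(0, config$segment_ms - 1, by = cycle_length)
  bounds <- c(stim, config$segment_ms)
  # analyzable beats: full QRS + T complex fits in the inter-stimulus
  # window (mirrors the feasibility guard in synth_electrogram)
  need <- max(lat) + max(ari_true) + 3 * tsig + 20
  n_beats <- sum((bounds[-1] - stim) >= need)
  if (n_beats < 2) abort("cycle length leaves fewer than 2 analyzable beats")

  ns <- length(sites)
  site_id <- sprintf("s%04d", seq_len(ns))
  truth <- tidyr::crossing(i = seq_len(ns), beat = seq_len(n_beats))
  truth$site_id <- site_id[truth$i]
  truth$node_id <- sites[truth$i]
  truth$at_ms <- stim[truth$beat] + lat[truth$i]
  truth$ari_ms <- ari_true[truth$i]
  truth$rt_ms <- truth$at_ms + truth$ari_ms
  truth$polarity <- anatomy$polarity[truth$i]
  truth <- truth[order(truth$i, truth$beat),
                 c("site_id", "node_id", "beat", "at_ms", "rt_ms",
                   "ari_ms", "polarity")]

  trunc_stim <- if (length(stim) > n_beats) stim[(n_beats + 1):length(stim)] else numeric()
  noise_seeds <- sample.int(.Machine$integer.max - 1, ns)
  uni <- vector("list", ns)
  for (i in seq_len(ns)) {
    tr_i <- truth[((i - 1) * n_beats + 1):(i * n_beats), ]
    uni[[i]] <- synth_electrogram(
      tr_i, stimulus_times = stim, segment_ms = config$segment_ms,
      sampling_rate = config$sampling_rate,
      noise_sd = config$noise_sd, seed = noise_seeds[i],
      t_sigma = tsig, extra_qrs_at = trunc_stim + lat[i])
  }
  # stand-in for the neighboring-pole subtraction: the adjacent pole sees
  # activation ~2 ms later
  shift <- max(1L, round(2 * config$sampling_rate / 1000))
  bip <- lapply(uni, function(v) v - c(rep(v[1], shift), head(v, -shift)))

  records <- tibble::tibble(
    site_id = site_id, node_id = sites,
    x = shell$coords[sites, 1], y = shell$coords[sites, 2],
    z = shell$coords[sites, 3],
    sampling_rate = config$sampling_rate, segment_ms = config$segment_ms,
    unipolar = uni, bipolar = bip,
    stimulus_times = rep(list(stim), ns))

  case <- structure(list(
    case_id = sprintf("pig%02d_%s_%d", pig, chamber, cycle_length),
    pig = pig,
    shell = shell,
    records = records,
    pacing_site = unname(shell$coords[pace_node, ]),
    pacing_chamber = chamber,
    cycle_length = cycle_length,
    sampling_rate = config$sampling_rate,
    segment_ms = config$segment_ms
  ), class = "map_case")
  list(case = case, truth = tibble::as_tibble(truth))
}

#' @export
print.map_case <- function(x, ...) {
  cat(sprintf("<map_case> %s: %d sites, %s pacing @ %d ms CL, shell %d nodes\n",
              x$case_id, nrow(x$records), x$pacing_chamber, x$cycle_length,
              n_nodes(x$shell)))
  invisible(x)
}

#' Generate a full synthetic study
#'
#' One case per pig x cycle length x chamber: RV pacing for all pigs,
#' LV endocardial pacing additionally for the first `lv_pigs` pigs,
#' sharing each pig's anatomy (shell, scar, sites, perturbation) across
#' its protocols.
#'
#' @param config A [synthetic_config()].
#' @return List with `cases` (named list of `map_case`) and `truth`
#'   (combined tibble with case_id column).
#' @export
make_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cases <- list(); truths <- list()
  for (pig in seq_len(config$n_pigs)) {
    anatomy <- make_pig_anatomy(config, pig)
    chambers <- if (pig <= config$lv_pigs) c("RV", "LV") else "RV"
    for (ch in chambers) {
      for (cl in config$cycle_lengths) {
        mc <- make_case(config, pig, cl, ch, anatomy = anatomy)
        cases[[mc$case$case_id]] <- mc$case
        mc$truth$case_id <- mc$case$case_id
        truths[[mc$case$case_id]] <- mc$truth
      }
    }
  }
  list(cases = cases, truth = dplyr::bind_rows(truths))
}

#' Validate a map case
#'
#' Checks the shell and record invariants: triangle indices in range,
#' trace length equal to `segment_ms * sampling_rate / 1000`, stimulus
#' times strictly increasing inside the segment and spaced by the cycle
#' length to within one sample.
#'
#' @param case A `map_case`.
#' @return Invisibly `case`; errors name the offending site or node.
#' @export
validate_case <- function(case) {
  if (case$cycle_length <= 0) abort("cycle_length must be > 0")
  sh <- case$shell
  if (nrow(sh$triangles) && max(sh$triangles) > n_nodes(sh)) {
    abort("shell triangle references a missing node")
  }
  tol_ms <- 1000 / case$sampling_rate
  n_expect <- round(case$segment_ms * case$sampling_rate / 1000)
  for (i in seq_len(nrow(case$records))) {
    r <- case$records[i, ]
    if (length(r$unipolar[[1]]) != n_expect) {
      abort(sprintf("site %s: trace length %d != %d", r$site_id,
                    length(r$unipolar[[1]]), n_expect))
    }
    st <- r$stimulus_times[[1]]
    if (any(diff(st) <= 0) || any(st < 0) || any(st >= case$segment_ms)) {
      abort(sprintf("site %s: stimulus times not increasing inside segment",
                    r$site_id))
    }
    if (length(st) > 1 && any(abs(diff(st) - case$cycle_length) > tol_ms)) {
      abort(sprintf("site %s: stimulus spacing differs from cycle length",
                    r$site_id))
    }
  }
  invisible(case)
}
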