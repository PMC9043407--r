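#' Detector configuration
#'
#' Constants for electrogram fiducial detection. Only the 80 Hz low-pass
#' cutoff and the 10 percent beat-consistency threshold are
#' literature-fixed; the window lengths and rejection floors are
#' documented package defaults, all configurable.
#'
#' @param lowpass_cutoff Low-pass cutoff, Hz (default 80).
#' @param qrs_window QRS search window after each stimulus, ms.
#' @param t_search_start_offset T-wave search start after the detected
#'   activation time, ms.
#' @param t_guard Margin kept before the next stimulus, ms.
#' @param min_t_window Minimum usable T-search window, ms; shorter beats
#'   are marked invalid.
#' @param min_bipolar_mv Minimum peak-to-peak bipolar amplitude in the QRS
#'   window; beats below it carry no local deflection and are invalid.
#' @param peak_floor_mv Minimum baseline-corrected T-peak amplitude to call
#'   a positive T wave; below it (or 3x the trace noise estimate,
#'   whichever is larger) the T wave is assumed negative.
#' @param flat_tol Derivative range below which a window counts as flat, mV.
#' @param t_deriv_smooth_ms SD (ms) of the Gaussian-derivative kernel used
#'   to localize the T-wave maximal slope; the known kernel (and analysis
#'   filter) broadening is removed analytically, so the reported fiducial
#'   is unbiased for a locally Gaussian T wave (see
#'   [detect_repolarization()]).
#' @param t_fit_halfwidth_ms Half-width (ms) of the local polynomial fit
#'   around the smoothed-derivative maximum.
#' @param consistency_threshold Relative first-vs-second-beat ARI
#'   difference above which a site is excluded (default 0.10).
#' @param beat_select Which beat's ARI represents a site: `"first"`
#'   (default), `"second"` or `"mean"` of the first two.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(lowpass_cutoff = 80, qrs_window = 150,
                            t_search_start_offset = 100, t_guard = 20,
                            min_t_window = 40, min_bipolar_mv = 0.1,
                            peak_floor_mv = 0.05, flat_tol = 1e-6,
                            t_deriv_smooth_ms = 8, t_fit_halfwidth_ms = 12,
                            consistency_threshold = 0.10,
                            beat_select = c("first", "second", "mean")) {
  if (consistency_threshold <= 0 || consistency_threshold >= 1) {
    abort("consistency_threshold must be in (0, 1).")
  }
  if (any(c(qrs_window, t_search_start_offset, t_guard, min_t_window) <= 0)) {
    abort("window lengths must be positive.")
  }
  cfg <- as.list(environment())
  cfg$beat_select <- match.arg(beat_select)
  class(cfg) <- "detector_config"
  cfg
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase, so
#' fiducial timing is preserved), with symmetric end-padding to suppress
#' edge transients. DC gain is 1.
#'
#' @param x Numeric trace.
#' @param sampling_rate Hz.
#' @param cutoff Cutoff frequency, Hz; must be below Nyquist.
#' @param order Filter order (default 4).
#' @return Filtered trace, same length.
#' @export
lowpass <- function(x, sampling_rate, cutoff = 80, order = 4) {
  ny <- sampling_rate / 2
  if (cutoff >= ny) {
    abort(sprintf("cutoff %.1f Hz must be below Nyquist (%.1f Hz)", cutoff, ny))
  }
  n <- length(x)
  bf <- signal::butter(order, cutoff / ny)
  np <- min(n - 1, 150)
  xp <- c(rev(x[2:(np + 1)]), x, rev(x[(n - np):(n - 1)]))
  f1 <- signal::filter(bf, xp)
  f2 <- rev(signal::filter(bf, rev(f1)))
  as.numeric(f2[(np + 1):(np + n)])
}

#' Bipolar electrogram from two unipolar traces
#'
#' @param unipolar_a,unipolar_b Equal-length traces from neighboring
#'   poles, mV.
#' @return Elementwise difference `a - b`.
#' @export
make_bipolar <- function(unipolar_a, unipolar_b) {
  if (length(unipolar_a) != length(unipolar_b)) {
    abort("unipolar traces must have equal length.")
  }
  unipolar_a - unipolar_b
}

#' Per-beat analysis windows for a one-second segment
#'
#' One window per stimulus, spanning to the next stimulus (or segment
#' end). A beat is provisionally analyzable when its window can hold a QRS
#' search window plus the start of a T search; truncated trailing
#' complexes are kept in the table but flagged.
#'
#' @param stimulus_times Stimulus times, ms, increasing.
#' @param segment_ms Segment length, ms.
#' @param config A [detector_config()].
#' @return Tibble: `beat`, `stim_ms`, `win_start_ms`, `win_end_ms`,
#'   `analyzable`. Warns when no beat is analyzable.
#' @export
segment_beats <- function(stimulus_times, segment_ms = 1000,
                          config = detector_config()) {
  if (length(stimulus_times) < 1) abort("at least one stimulus is required.")
  stim <- sort(stimulus_times)
  ends <- c(stim[-1], segment_ms)
  min_len <- config$qrs_window + config$t_search_start_offset
  ok <- (ends - stim) >= min_len
  out <- tibble::new_tibble(list(
    beat = seq_along(stim), stim_ms = stim,
    win_start_ms = stim, win_end_ms = ends,
    analyzable = ok), nrow = length(stim))
  if (!any(ok)) warn("no analyzable beats in segment")
  out
}

# central-difference derivative, mV per ms
trace_derivative <- function(x, sampling_rate) {
  n <- length(x)
  d <- numeric(n)
  dt <- 1000 / sampling_rate
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

ms_to_idx <- function(ms, sampling_rate) round(ms * sampling_rate / 1000) + 1L
idx_to_ms <- function(idx, sampling_rate) (idx - 1L) * 1000 / sampling_rate

# Derivative of the Gaussian-smoothed trace (kernel SD `w` in samples),
# normalized to unit response on a slope-1 ramp. NA at the ends.
gaussian_deriv <- function(x, w) {
  hw <- ceiling(3 * w)
  u <- (-hw):hw
  k <- u / w^2 * exp(-u^2 / (2 * w^2))
  k <- k / sum(u * k)
  as.numeric(stats::filter(x, rev(k), sides = 2))
}

# Locate the maximal upslope of a smooth peak flank within idx range
# [i0, i1]. The smoothed-derivative maximum is refined by a local cubic
# fit (stationary point), and the known broadening of the smoothing
# kernel plus analysis filter is removed under a locally Gaussian flank
# model: a Gaussian flank of scale s observed through a kernel of scale w
# has its maximal slope displaced from the true one by
# sqrt(s^2 + w^2) - s toward the far side of the peak; `sign` = +1 when
# the true point precedes the observed one (upslope before a positive
# peak), -1 for the mirrored case.
wyatt_upslope <- function(uf, i0, i1, sign, sampling_rate, config,
                          deriv_smooth = NULL) {
  sr_ms <- sampling_rate / 1000
  w <- config$t_deriv_smooth_ms * sr_ms
  L <- max(3L, as.integer(round(config$t_fit_halfwidth_ms * sr_ms)))
  d <- deriv_smooth %||% gaussian_deriv(uf, w)
  dv <- d[i0:i1]
  if (all(is.na(dv))) return(NA_integer_)
  dv[is.na(dv)] <- -Inf
  ic <- i0 + which.max(dv) - 1L
  rr <- max(i0, ic - L):min(i1, ic + L)
  rr <- rr[is.finite(d[rr])]
  if (length(rr) < 5) return(ic)
  u <- rr - ic
  X <- cbind(1, u, u^2, u^3)
  co <- tryCatch(as.numeric(solve(crossprod(X), crossprod(X, d[rr]))),
                 error = function(e) rep(NA_real_, 4))
  if (anyNA(co) || co[3] >= 0) return(ic)
  disc <- 4 * co[3]^2 - 12 * co[2] * co[4]
  v <- if (abs(co[4]) < 1e-12 || disc < 0) {
    -co[2] / (2 * co[3])
  } else {
    r <- c((-2 * co[3] + sqrt(disc)) / (6 * co[4]),
           (-2 * co[3] - sqrt(disc)) / (6 * co[4]))
    r[which.min(abs(r))]
  }
  v <- max(min(v, L), -L)
  P <- co[1] + co[2] * v + co[3] * v^2 + co[4] * v^3
  sc2 <- P / (-co[3])
  wf <- 176 / config$lowpass_cutoff * sr_ms  # zero-phase Butterworth broadening
  we2 <- w^2 + wf^2
  corr <- if (is.finite(sc2) && sc2 > we2) {
    sqrt(sc2) - sqrt(sc2 - we2)
  } else if (is.finite(sc2) && sc2 > 0) sqrt(sc2) else 0
  as.integer(round(ic + v + sign * corr))
}

#' Detect local activation time
#'
#' Activation is the time of the maximal negative derivative of the
#' (filtered) unipolar electrogram within the QRS search window. The
#' bipolar trace is used only to reject windows with no local deflection
#' (peak-to-peak below `min_bipolar_mv`). Ties break toward the earliest
#' sample.
#'
#' @param unipolar_f Low-pass-filtered unipolar trace.
#' @param bipolar Bipolar trace (or NULL to skip the amplitude check).
#' @param window_ms Length-2 numeric, search window in ms.
#' @param sampling_rate Hz.
#' @param config A [detector_config()].
#' @return List: `at_ms` (NA when invalid), `valid`, `reason`.
#' @export
detect_activation <- function(unipolar_f, bipolar, window_ms, sampling_rate,
                              config = detector_config(), deriv = NULL) {
  i0 <- max(1L, ms_to_idx(window_ms[1], sampling_rate))
  i1 <- min(length(unipolar_f), ms_to_idx(window_ms[2], sampling_rate))
  if (i1 - i0 < 2) return(list(at_ms = NA_real_, valid = FALSE, reason = "window"))
  w <- unipolar_f[i0:i1]
  if (diff(range(w)) < config$flat_tol) {
    return(list(at_ms = NA_real_, valid = FALSE, reason = "flat"))
  }
  if (!is.null(bipolar)) {
    bw <- bipolar[i0:i1]
    if (diff(range(bw)) < config$min_bipolar_mv) {
      return(list(at_ms = NA_real_, valid = FALSE, reason = "no_deflection"))
    }
  }
  d <- (deriv %||% trace_derivative(unipolar_f, sampling_rate))[i0:i1]
  at_idx <- i0 + which.min(d) - 1L
  list(at_ms = idx_to_ms(at_idx, sampling_rate), valid = TRUE, reason = "ok")
}

#' Detect repolarization time (Wyatt fiducial)
#'
#' Searches `[at + t_search_start_offset, window_end - t_guard]`. The
#' T peak is the largest interior local maximum of the window after
#' removing its median baseline; when no local maximum exceeds
#' `max(3 x noise estimate, peak_floor_mv)` the T wave is assumed
#' negative and the negative peak (trough) is used. Positive T:
#' repolarization is the maximal derivative before the peak; negative T:
#' the maximal derivative after the trough.
#'
#' @param unipolar_f Filtered unipolar trace.
#' @param at_ms Detected activation time, ms.
#' @param window_end_ms End of this beat's window, ms (next stimulus or
#'   segment end).
#' @param sampling_rate Hz.
#' @param config A [detector_config()].
#' @param noise_mv Trace noise estimate, mV (0 for noise-free data).
#' @return List: `rt_ms`, `polarity`, `valid`, `reason`.
#' @export
detect_repolarization <- function(unipolar_f, at_ms, window_end_ms,
                                  sampling_rate,
                                  config = detector_config(),
                                  noise_mv = 0, deriv_smooth = NULL) {
  t0 <- at_ms + config$t_search_start_offset
  t1 <- window_end_ms - config$t_guard
  if (t1 - t0 < config$min_t_window) {
    return(list(rt_ms = NA_real_, polarity = NA_character_,
                valid = FALSE, reason = "t_window"))
  }
  i0 <- max(1L, ms_to_idx(t0, sampling_rate))
  i1 <- min(length(unipolar_f), ms_to_idx(t1, sampling_rate))
  w <- unipolar_f[i0:i1]
  m <- length(w)
  # robust level baseline: the median is insensitive to the T wave itself
  # even when a flank touches the window edge
  xs <- w - median(w)
  thr <- max(3 * noise_mv, config$peak_floor_mv)
  interior <- 2:(m - 1)
  is_max <- xs[interior] >= xs[interior - 1] & xs[interior] >= xs[interior + 1]
  cand <- interior[is_max & xs[interior] > thr]
  if (length(cand)) {
    peak <- cand[which.max(xs[cand])]
    rt_idx <- wyatt_upslope(unipolar_f, i0, i0 + peak - 1L, +1,
                            sampling_rate, config, deriv_smooth)
    pol <- "positive"
  } else {
    is_min <- xs[interior] <= xs[interior - 1] & xs[interior] <= xs[interior + 1]
    cmin <- interior[is_min & xs[interior] < -thr]
    trough <- if (length(cmin)) cmin[which.min(xs[cmin])] else which.min(xs)
    rt_idx <- wyatt_upslope(unipolar_f, i0 + trough - 1L, i1, -1,
                            sampling_rate, config, deriv_smooth)
    pol <- "negative"
  }
  if (is.na(rt_idx)) {
    return(list(rt_ms = NA_real_, polarity = pol, valid = FALSE,
                reason = "no_upslope"))
  }
  rt_ms <- idx_to_ms(rt_idx, sampling_rate)
  if (rt_ms <= at_ms) {
    return(list(rt_ms = NA_real_, polarity = pol, valid = FALSE,
                reason = "rt_before_at"))
  }
  list(rt_ms = rt_ms, polarity = pol, valid = TRUE, reason = "ok")
}

#' Annotate all beats of one electrogram
#'
#' Runs filtering, beat segmentation, activation and repolarization
#' detection, and ARI computation (`ari = rt - at`) for one site.
#'
#' @param unipolar Raw unipolar trace, mV.
#' @param bipolar Bipolar trace or NULL.
#' @param stimulus_times Stimulus times, ms.
#' @param sampling_rate Hz.
#' @param segment_ms Segment length, ms.
#' @param config A [detector_config()].
#' @return Tibble: `beat`, `at_ms`, `rt_ms`, `ari_ms`, `polarity`,
#'   `valid`, `reason`.
#' @export
annotate_beats <- function(unipolar, bipolar = NULL, stimulus_times,
                           sampling_rate = 1000, segment_ms = 1000,
                           config = detector_config()) {
  uf <- lowpass(unipolar, sampling_rate, config$lowpass_cutoff)
  noise_mv <- mad(unipolar - uf)
  deriv <- trace_derivative(uf, sampling_rate)
  dsm <- gaussian_deriv(uf, config$t_deriv_smooth_ms * sampling_rate / 1000)
  beats <- segment_beats(stimulus_times, segment_ms, config)
  nb <- nrow(beats)
  at <- rt <- ari <- rep(NA_real_, nb)
  pol <- rep(NA_character_, nb)
  valid <- rep(FALSE, nb)
  reason <- rep("not_analyzable", nb)
  for (i in seq_len(nb)) {
    if (!beats$analyzable[i]) next
    act <- detect_activation(uf, bipolar,
                             c(beats$stim_ms[i], beats$stim_ms[i] + config$qrs_window),
                             sampling_rate, config, deriv)
    if (!act$valid) { reason[i] <- act$reason; next }
    at[i] <- act$at_ms
    rp <- detect_repolarization(uf, act$at_ms, beats$win_end_ms[i],
                                sampling_rate, config, noise_mv, dsm)
    reason[i] <- rp$reason
    pol[i] <- rp$polarity %||% NA_character_
    if (rp$valid) {
      rt[i] <- rp$rt_ms
      ari[i] <- rp$rt_ms - act$at_ms
      valid[i] <- TRUE
    }
  }
  tibble::new_tibble(list(beat = beats$beat, at_ms = at, rt_ms = rt,
                          ari_ms = ari, polarity = pol, valid = valid,
                          reason = reason), nrow = nb)
}

#' Fiducials for every site of a case
#'
#' @param case A `map_case`.
#' @param config A [detector_config()].
#' @return Tibble of per-site, per-beat annotations (`site_id` + the
#'   columns of [annotate_beats()]).
#' @export
egm_fiducials <- function(case, config = detector_config()) {
  recs <- case$records
  out <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    ann <- annotate_beats(recs$unipolar[[i]],
                          recs$bipolar[[i]] %||% NULL,
                          recs$stimulus_times[[i]],
                          recs$sampling_rate[i], recs$segment_ms[i], config)
    ann$site_id <- recs$site_id[i]
    out[[i]] <- ann
  }
  dplyr::relocate(dplyr::bind_rows(out), "site_id")
}

#' Beat-consistency filter
#'
#' A site is kept only when the ARI of its second beat differs from the
#' first by at most `threshold` (relative, strict inequality: exactly at
#' the threshold is kept). Sites with fewer than two valid beats cannot be
#' checked and are dropped; a zero first-beat ARI drops the site with a
#' warning.
#'
#' @param annotations Output of [egm_fiducials()].
#' @param threshold Relative difference threshold (default 0.10).
#' @return Tibble: `site_id`, `ari1_ms`, `ari2_ms`, `rel_diff`, `kept`.
#' @export
consistency_filter <- function(annotations, threshold = 0.10) {
  ann <- dplyr::filter(annotations, .data$valid)
  per_site <- dplyr::summarise(
    dplyr::group_by(ann, .data$site_id),
    ari1_ms = .data$ari_ms[match(1L, .data$beat)],
    ari2_ms = .data$ari_ms[match(2L, .data$beat)],
    .groups = "drop")
  all_sites <- tibble::tibble(site_id = unique(annotations$site_id))
  per_site <- dplyr::left_join(all_sites, per_site, by = "site_id")
  per_site$rel_diff <- abs(per_site$ari2_ms - per_site$ari1_ms) / per_site$ari1_ms
  zero1 <- !is.na(per_site$ari1_ms) & per_site$ari1_ms == 0
  if (any(zero1)) warn(sprintf("%d site(s) with zero first-beat ARI dropped", sum(zero1)))
  per_site$kept <- !is.na(per_site$ari1_ms) & !is.na(per_site$ari2_ms) &
    !zero1 & per_site$rel_diff <= threshold
  per_site
}

#' Per-site ARI after beat selection
#'
#' Reduces kept sites to one ARI (and activation/repolarization time) per
#' site: the first beat, the second, or the mean of the first two.
#'
#' @param annotations Output of [egm_fiducials()].
#' @param config A [detector_config()]; `beat_select` and
#'   `consistency_threshold` are used.
#' @return Tibble: `site_id`, `at_ms`, `rt_ms`, `ari_ms` — filtered sites
#'   are absent.
#' @export
site_ari <- function(annotations, config = detector_config()) {
  keep <- consistency_filter(annotations, config$consistency_threshold)
  kept_ids <- keep$site_id[keep$kept]
  ann <- dplyr::filter(annotations, .data$valid,
                       .data$site_id %in% kept_ids, .data$beat <= 2L)
  sel <- config$beat_select
  dplyr::summarise(
    dplyr::group_by(ann, .data$site_id),
    at_ms = switch(sel,
      first = .data$at_ms[.data$beat == 1L],
      second = .data$at_ms[.data$beat == 2L],
      mean = mean(.data$at_ms)),
    rt_ms = switch(sel,
      first = .data$rt_ms[.data$beat == 1L],
      second = .data$rt_ms[.data$beat == 2L],
      mean = mean(.data$rt_ms)),
    ari_ms = switch(sel,
      first = .data$ari_ms[.data$beat == 1L],
      second = .data$ari_ms[.data$beat == 2L],
      mean = mean(.data$ari_ms)),
    .groups = "drop")
}
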