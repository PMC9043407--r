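#' Synthesize a unipolar electrogram with known fiducials
#'
#' Builds a sampled unipolar trace from per-beat ground-truth fiducials.
#' Each beat is drawn inside its own inter-stimulus window as a negative
#' logistic QRS step plus a Gaussian T wave; the level reset at each
#' stimulus plays the role of the pacing artifact. The templates are chosen
#' so the detector fiducials are analytically exact:
#'
#' * the steepest negative slope of the logistic step falls exactly at the
#'   true activation time (`at_ms`);
#' * a positive T wave has its peak at `rt_ms + t_sigma`, so the maximal
#'   upslope before the peak (the Wyatt point) falls at `rt_ms`;
#' * a negative T wave has its trough at `rt_ms - t_sigma`, so the maximal
#'   upslope after the trough falls at `rt_ms`.
#'
#' @param truth Data frame with one row per analyzable beat: `beat`
#'   (1-based, matching `stimulus_times` order), `at_ms`, `rt_ms`,
#'   `polarity` (`"positive"`/`"negative"`).
#' @param stimulus_times Pacing stimulus times, ms, strictly increasing in
#'   `[0, segment_ms)`.
#' @param segment_ms Segment length (default 1000 ms).
#' @param sampling_rate Hz (default 1000).
#' @param noise_sd SD of additive white Gaussian noise, mV.
#' @param seed Optional integer seed for the noise.
#' @param qrs_amp,qrs_slope_width QRS step amplitude (mV) and slope width
#'   (ms); the logistic scale is `qrs_slope_width / 4` so the central slope
#'   is `qrs_amp / qrs_slope_width`.
#' @param t_amp,t_sigma T-wave amplitude (mV) and Gaussian SD (ms).
#' @param t_guard Margin, ms, required between T-wave support
#'   and the end of the beat window; violation raises an
#'   "infeasible truth" error.
#' @param extra_qrs_at Activation times of truncated trailing complexes
#'   (QRS only, no T wave), e.g. a fourth stimulus at 900 ms in a 1-s
#'   segment at 300 ms cycle length.
#' @return Numeric vector of length `segment_ms * sampling_rate / 1000`.
#' @export
synth_electrogram <- function(truth, stimulus_times, segment_ms = 1000,
                              sampling_rate = 1000, noise_sd = 0,
                              seed = NULL,
                              qrs_amp = 2, qrs_slope_width = 5,
                              t_amp = 0.5, t_sigma = 25, t_guard = 20,
                              extra_qrs_at = numeric()) {
  n <- round(segment_ms * sampling_rate / 1000)
  tt <- (seq_len(n) - 1) * 1000 / sampling_rate
  v <- numeric(n)
  s <- qrs_slope_width / 4
  stim <- sort(stimulus_times)
  bounds <- c(stim, segment_ms)
  for (i in seq_len(nrow(truth))) {
    b <- truth$beat[i]
    if (b > length(stim)) abort("truth beat index beyond stimulus count")
    w0 <- bounds[b]; w1 <- bounds[b + 1]
    at <- truth$at_ms[i]; rt <- truth$rt_ms[i]
    pol <- if (truth$polarity[i] == "negative") -1 else 1
    mu <- rt + pol * t_sigma
    if (at <= w0 || rt <= at) abort("infeasible truth: fiducial order")
    if (mu + 2 * t_sigma > w1 - t_guard) {
      abort(sprintf("infeasible truth: beat %d T wave (peak %.1f ms) collides with window end %.1f ms",
                    b, mu, w1))
    }
    idx <- tt >= w0 & tt < w1
    tw <- tt[idx]
    v[idx] <- v[idx] - qrs_amp / (1 + exp(-(tw - at) / s)) +
      pol * t_amp * exp(-(tw - mu)^2 / (2 * t_sigma^2))
  }
  for (at in extra_qrs_at) {
    b <- findInterval(at, bounds)
    w0 <- bounds[b]; w1 <- bounds[b + 1]
    idx <- tt >= w0 & tt < w1
    v[idx] <- v[idx] - qrs_amp / (1 + exp(-(tt[idx] - at) / s))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
      set.seed(as.integer(seed))
    }
    v <- v + rnorm(n, sd = noise_sd)
  }
  v
}
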