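# Audio--accelerometer clock alignment via the hand-clap event, plus
# throw-artifact masking.
#
# Caregivers clap five times at the start of each session; the claps are
# sharp broadband transients visible both in the room audio and in the
# caregiver-hand accelerometers. The lag between the two clocks is the
# argmax of the normalised cross-correlation between the audio amplitude
# envelope and the mean hand acceleration magnitude envelope, both at a
# common rate (60 Hz), refined to sub-sample precision by parabolic
# interpolation.

#' Synchronisation / QC configuration
#'
#' @param expected_claps number of claps in the synchronisation event.
#' @param clap_k adaptive clap threshold: `median + clap_k * MAD` of the
#'   short-time audio envelope.
#' @param min_spacing minimum spacing between detected claps, seconds.
#' @param search_s claps are searched within the first `search_s` seconds.
#' @param common_rate rate (Hz) at which envelopes are cross-correlated.
#' @param max_lag cross-correlation search window, seconds.
#' @param min_quality minimum acceptable normalised peak correlation.
#' @param envelope_smooth_s moving-average smoothing applied to both
#'   envelopes before correlation, seconds.
#' @return a list of class `sync_config`.
#' @export
sync_config <- function(expected_claps = 5, clap_k = 8, min_spacing = 0.15,
                        search_s = 60, common_rate = 60, max_lag = 10,
                        min_quality = 0.5, envelope_smooth_s = 0.05) {
  structure(as.list(environment()), class = "sync_config")
}

# Short-time amplitude envelope of audio at its native rate.
audio_envelope <- function(audio, win_s = 0.005) {
  moving_average(abs(audio$samples), max(3L, round(win_s * audio$rate)))
}

# Bin-RMS the audio down to `rate` Hz; returns list(t, value).
audio_envelope_at <- function(audio, rate) {
  n_bin <- floor(length(audio$samples) / (audio$rate / rate))
  per <- audio$rate / rate
  idx <- floor((seq_along(audio$samples) - 1L) / per) + 1L
  keep <- idx <= n_bin
  v <- sqrt(tapply(audio$samples[keep]^2, idx[keep], mean))
  list(t = audio$t0 + (seq_len(n_bin) - 0.5) / rate, value = as.numeric(v))
}

#' Detect hand claps in session audio
#'
#' Peaks of the short-time amplitude envelope exceeding an adaptive
#' threshold (`median + clap_k * MAD`), separated by at least
#' `min_spacing`, within the first `search_s` seconds.
#'
#' @param audio an [audio_track()].
#' @param config a [sync_config()].
#' @return a data frame with columns `time` (s) and `prominence`.
#' @export
detect_claps <- function(audio, config = sync_config()) {
  if (length(audio$samples) == 0L) stop_fmt("detect_claps: empty audio")
  env <- audio_envelope(audio)
  thr <- median(env) + config$clap_k * mad(env)
  lim <- min(length(env), round(config$search_s * audio$rate))
  seg <- env[seq_len(lim)]
  sep <- max(2L, round(config$min_spacing * audio$rate))
  pk <- find_peaks(seg, min_sep = sep)
  pk <- pk[seg[pk] > thr]
  times <- audio$t0 + (pk - 1L) / audio$rate
  out <- data.frame(time = times, prominence = seg[pk] - thr)
  if (nrow(out) < config$expected_claps)
    stop_fmt("detect_claps: expected %d claps, found %d (times: %s)",
             config$expected_claps, nrow(out),
             if (nrow(out)) paste(sprintf("%.2f", out$time), collapse = ", ")
             else "none")
  out
}

# Mean caregiver-hand magnitude envelope on a uniform grid at `rate`,
# centred (median removed) and rectified. Returns list(t, value).
hand_envelope_at <- function(channels, rate) {
  if (!length(channels)) stop_fmt("estimate_lag: no caregiver hand channels")
  t0 <- max(vapply(channels, function(ch) ch$t[1L], numeric(1)))
  t1 <- min(vapply(channels, function(ch) ch$t[length(ch$t)], numeric(1)))
  grid <- seq(t0, t1, by = 1 / rate)
  mags <- vapply(channels, function(ch) {
    m <- sqrt(ch$x^2 + ch$y^2 + ch$z^2)
    ok <- is.finite(m)
    approx(ch$t[ok], m[ok], xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  m <- rowMeans(as.matrix(mags))
  list(t = grid, value = abs(m - median(m)))
}

#' Estimated audio--accelerometer lag
#'
#' Detects the clap burst in the audio, then slides the audio amplitude
#' envelope restricted to the burst (plus a small margin) along the mean
#' caregiver-hand magnitude envelope, both at `common_rate`; the lag is the
#' argmax of the normalised (Pearson) cross-correlation, refined to
#' sub-sample precision by parabolic interpolation. Restricting to the
#' burst keeps vocalisations and other room sound out of the template.
#'
#' Positive lag means the accelerometer clock is behind the audio clock:
#' adding `lag` to accelerometer timestamps aligns them with the audio.
#'
#' @param audio an [audio_track()] containing the clap burst.
#' @param hand_channels list of caregiver-hand [acc_channel()]s.
#' @param config a [sync_config()].
#' @return a list of class `lag_estimate` with `lag` (s), `peak_corr`,
#'   and `quality` (`"ok"` or `"low"`).
#' @export
estimate_lag <- function(audio, hand_channels, config = sync_config()) {
  if (inherits(hand_channels, "acc_channel"))
    hand_channels <- list(hand_channels)
  rate <- config$common_rate
  claps <- detect_claps(audio, config)
  t_lo <- min(claps$time) - 2
  t_hi <- max(claps$time) + 2
  ea <- audio_envelope_at(audio, rate)
  eh <- hand_envelope_at(hand_channels, rate)
  smooth_n <- max(1L, round(config$envelope_smooth_s * rate))
  a_all <- moving_average(ea$value, smooth_n)
  h_all <- moving_average(eh$value, smooth_n)
  a_sel <- ea$t >= t_lo & ea$t <= t_hi
  h_sel <- eh$t >= t_lo - config$max_lag & eh$t <= t_hi + config$max_lag
  a <- a_all[a_sel]
  h <- h_all[h_sel]
  ta0 <- ea$t[a_sel][1L]
  th0 <- eh$t[h_sel][1L]
  na <- length(a)
  if (length(h) <= na + 2L)
    stop_fmt("estimate_lag: hand recording too short around the clap burst")
  offsets <- 0:(length(h) - na)
  r <- vapply(offsets, function(j)
    suppressWarnings(stats::cor(a, h[(j + 1L):(j + na)])), numeric(1))
  r[!is.finite(r)] <- -1
  i <- which.max(r)
  pp <- parabolic_peak(r, i)
  j_star <- offsets[i] + pp$delta
  lag <- ta0 - th0 - j_star / rate
  peak_corr <- max(-1, min(1, pp$value))
  quality <- if (is.finite(peak_corr) && peak_corr >= config$min_quality)
    "ok" else "low"
  if (quality == "low")
    stop_fmt("estimate_lag: low-confidence alignment (peak correlation %.2f < %.2f)",
             peak_corr, config$min_quality)
  structure(list(lag = lag, peak_corr = peak_corr, quality = quality),
            class = "lag_estimate")
}

#' Shift accelerometer channels onto the audio clock
#'
#' Adds `lag` seconds to every timestamp. Composes additively:
#' `apply_lag(apply_lag(ch, a), b)` equals `apply_lag(ch, a + b)`.
#'
#' @param channels an [acc_channel()], [magnitude_series()], or a list of
#'   either.
#' @param lag lag in seconds (finite).
#' @return the shifted object(s).
#' @export
apply_lag <- function(channels, lag) {
  if (!is.finite(lag)) stop_fmt("apply_lag: lag must be finite")
  shift1 <- function(ch) { ch$t <- ch$t + lag; ch }
  if (inherits(channels, c("acc_channel", "magnitude_series")))
    return(shift1(channels))
  lapply(channels, shift1)
}

#' Mask throw artifacts in a magnitude series
#'
#' Samples whose absolute value exceeds `threshold` are masked, with a
#' guard margin dilated on each side. Contiguous masked runs longer than
#' `max_len` are reported in the `long_runs` attribute (flagged for QC) but
#' remain masked. The default threshold is data-driven:
#' `median + 10 * MAD` of the series, mirroring empirical calibration
#' against sensor-throw events.
#'
#' @param series a [magnitude_series()] or numeric vector.
#' @param threshold absolute threshold in m/s^2; `NULL` for the data-driven
#'   default.
#' @param max_len maximum expected artifact length, seconds (default 0.6).
#' @param guard guard margin, seconds, dilated on each side (default 0.05).
#' @param rate sampling rate; taken from `series` when it is a
#'   `magnitude_series`.
#' @return logical mask, with attribute `long_runs` (data frame of runs
#'   exceeding `max_len`, possibly empty).
#' @export
detect_artifacts <- function(series, threshold = NULL, max_len = 0.6,
                             guard = 0.05, rate = NULL) {
  if (inherits(series, "magnitude_series")) {
    v <- series$value
    rate <- series$rate
  } else {
    v <- as.numeric(series)
    if (is.null(rate)) stop_fmt("detect_artifacts: rate required for raw vectors")
  }
  if (is.null(threshold)) threshold <- median(v) + 10 * mad(v)
  if (threshold <= 0) stop_fmt("detect_artifacts: threshold must be positive")
  mask <- abs(v) > threshold
  mask <- dilate_mask(mask, round(guard * rate))
  runs <- true_runs(mask)
  long <- runs[(runs$end - runs$start + 1L) / rate > max_len, , drop = FALSE]
  attr(mask, "long_runs") <- long
  attr(mask, "threshold") <- threshold
  mask
}
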