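# Raw 3-axis channels -> filtered acceleration magnitude series.
#
# Processing order mirrors standard actigraphy practice: interpolate dropped
# packets, resample to the nominal 60 Hz grid, take the Euclidean magnitude
# Acc(t) = sqrt(x^2 + y^2 + z^2), then remove the quasi-static (gravity)
# component with a 2nd-order 1 Hz highpass Butterworth filter.

#' Acceleration magnitude series
#'
#' @param t sample times, seconds.
#' @param value magnitude in m/s^2 (may be negative after highpassing).
#' @param rate sampling rate in Hz.
#' @param mask logical; TRUE where the value derives from interpolated or
#'   artifact-contaminated data.
#' @param placement a [placement()].
#' @return an object of class `magnitude_series`.
#' @export
magnitude_series <- function(t, value, rate, placement,
                             mask = rep(FALSE, length(t))) {
  if (length(t) != length(value) || length(t) != length(mask))
    stop_fmt("magnitude_series: t, value, mask must have equal length")
  structure(list(t = as.numeric(t), value = as.numeric(value),
                 rate = as.numeric(rate), mask = as.logical(mask),
                 placement = placement),
            class = "magnitude_series")
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf("<magnitude_series> %s: %d samples @ %g Hz, %.1f%% masked\n",
              placement_id(x$placement), length(x$t), x$rate,
              100 * mean(x$mask)))
  invisible(x)
}

#' Interpolate dropped packets by cubic spline
#'
#' Fills `NA`/masked samples in each axis with a cubic spline fitted to the
#' valid samples (exact on cubic polynomial segments). The gap mask is
#' preserved so interpolated stretches remain visible to downstream QC.
#' Masked samples at the record boundary cannot be interpolated and are
#' trimmed with a warning.
#'
#' @param channel an [acc_channel()].
#' @return an [acc_channel()] with finite x, y, z everywhere.
#' @export
fill_gaps <- function(channel) {
  mask <- channel$gap_mask
  if (!any(mask)) return(channel)
  n <- length(mask)
  valid <- which(!mask)
  if (length(valid) < 4L)
    stop_fmt("fill_gaps: need at least 4 valid samples")
  first <- valid[1L]; last <- valid[length(valid)]
  if (first > 1L || last < n) {
    warn_fmt("fill_gaps: trimming %d boundary sample(s) that cannot be interpolated",
             (first - 1L) + (n - last))
    idx <- first:last
    channel <- acc_channel(channel$t[idx], channel$x[idx], channel$y[idx],
                           channel$z[idx], channel$rate, channel$placement,
                           channel$gap_mask[idx])
    mask <- channel$gap_mask
    if (!any(mask)) return(channel)
    valid <- which(!mask)
  }
  hole <- which(mask)
  for (ax in c("x", "y", "z")) {
    v <- channel[[ax]]
    v[hole] <- spline(channel$t[valid], v[valid], xout = channel$t[hole],
                      method = "fmm")$y
    channel[[ax]] <- v
  }
  channel
}

# Is the time base uniform at the stated rate (within tolerance)?
is_uniform <- function(t, rate, tol = 1e-6) {
  if (length(t) < 3L) return(TRUE)
  dt <- diff(t)
  max(abs(dt - 1 / rate)) < tol / rate + 1e-9
}

#' Resample a channel to a target rate
#'
#' Uniform input is converted by polyphase (FIR rational) resampling;
#' non-uniform input — e.g. a recording containing a 60 to 40 Hz rate-drop
#' segment — is interpolated onto the uniform target grid with a cubic
#' spline. The gap mask is propagated by neighbourhood: a target sample is
#' masked if any source sample within one source interval of it was masked.
#'
#' @param channel an [acc_channel()] with gaps already filled.
#' @param target_rate target rate in Hz (default 60).
#' @return an [acc_channel()] on a uniform grid at `target_rate`.
#' @export
resample_to_rate <- function(channel, target_rate = 60) {
  if (channel$rate == target_rate && is_uniform(channel$t, channel$rate))
    return(channel)
  if (any(!is.finite(channel$x)))
    stop_fmt("resample_to_rate: fill gaps before resampling")
  t0 <- channel$t[1L]
  t_end <- channel$t[length(channel$t)]
  new_t <- seq(t0, t_end, by = 1 / target_rate)
  if (is_uniform(channel$t, channel$rate)) {
    frac <- target_rate / channel$rate
    pq <- rational_approx(frac)
    res <- lapply(c("x", "y", "z"), function(ax)
      as.numeric(signal::resample(channel[[ax]], pq[1], pq[2])))
    # polyphase output is on the target grid anchored at t0
    n_new <- length(new_t)
    vals <- lapply(res, function(v) v[seq_len(min(n_new, length(v)))])
    n_new <- min(lengths(vals))
    new_t <- new_t[seq_len(n_new)]
    x <- vals[[1]][seq_len(n_new)]
    y <- vals[[2]][seq_len(n_new)]
    z <- vals[[3]][seq_len(n_new)]
  } else {
    x <- spline(channel$t, channel$x, xout = new_t, method = "fmm")$y
    y <- spline(channel$t, channel$y, xout = new_t, method = "fmm")$y
    z <- spline(channel$t, channel$z, xout = new_t, method = "fmm")$y
  }
  src_dt <- median(diff(channel$t))
  mask <- mask_to_grid(channel$t[channel$gap_mask], new_t, src_dt)
  acc_channel(new_t, x, y, z, rate = target_rate,
              placement = channel$placement, gap_mask = mask)
}

# Nearest-neighbour mask propagation: target samples within `radius` of any
# masked source time become masked.
mask_to_grid <- function(masked_times, new_t, radius) {
  mask <- rep(FALSE, length(new_t))
  if (!length(masked_times)) return(mask)
  for (tm in masked_times)
    mask[abs(new_t - tm) <= radius] <- TRUE
  mask
}

# Best small-denominator rational approximation of a ratio.
rational_approx <- function(frac, max_den = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in 1:max_den) {
    p <- round(frac * q)
    if (p < 1) next
    e <- abs(frac - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(p), q) }
    if (err < 1e-12) break
  }
  best
}

#' Euclidean magnitude of a 3-axis channel
#'
#' `Acc(t) = sqrt(x(t)^2 + y(t)^2 + z(t)^2)` per sample; placement and gap
#' mask are carried through.
#'
#' @param channel an [acc_channel()] on a uniform grid.
#' @return a [magnitude_series()].
#' @export
magnitude <- function(channel) {
  magnitude_series(channel$t,
                   sqrt(channel$x^2 + channel$y^2 + channel$z^2),
                   channel$rate, channel$placement, channel$gap_mask)
}

#' Highpass-filter a magnitude series
#'
#' 2nd-order Butterworth highpass (1 Hz cutoff by default), applied
#' forward-backward (zero phase) so that event-locked timing is not shifted
#' by filter group delay. A single-pass option is retained.
#'
#' @param series a [magnitude_series()] on a uniform grid.
#' @param cutoff cutoff frequency in Hz.
#' @param order filter order.
#' @param zero_phase apply forward-backward (`TRUE`, default) or single-pass.
#' @return a [magnitude_series()]; values may be negative (DC removed).
#' @export
highpass <- function(series, cutoff = 1, order = 2, zero_phase = TRUE) {
  n <- length(series$value)
  if (n <= 10L * order || n < 3L * round(series$rate / cutoff))
    stop_fmt("highpass: series too short (%d samples) for stable filtering", n)
  bf <- signal::butter(order, cutoff / (series$rate / 2), type = "high")
  v <- if (zero_phase) as.numeric(signal::filtfilt(bf, series$value))
       else as.numeric(signal::filter(bf, series$value))
  magnitude_series(series$t, v, series$rate, series$placement, series$mask)
}

#' Squared-magnitude Butterworth highpass response
#'
#' Analytic `|H(f)|^2` of an order-`order` Butterworth highpass — the
#' amplitude response of the zero-phase (forward-backward) filter.
#'
#' @param f frequency in Hz.
#' @param cutoff cutoff in Hz.
#' @param order filter order.
#' @return response values in `[0, 1]`.
#' @export
butter_highpass_gain2 <- function(f, cutoff = 1, order = 2) {
  r <- (f / cutoff)^(2 * order)
  r / (1 + r)
}

#' Full preprocessing chain for one channel
#'
#' [fill_gaps()] then [resample_to_rate()] then [magnitude()] then
#' [highpass()], with an optional artifact mask OR-ed into the series mask.
#'
#' @param channel an [acc_channel()].
#' @param target_rate uniform grid rate in Hz.
#' @param cutoff,order,zero_phase highpass parameters, see [highpass()].
#' @return a [magnitude_series()].
#' @export
preprocess_channel <- function(channel, target_rate = 60, cutoff = 1,
                               order = 2, zero_phase = TRUE) {
  ch <- fill_gaps(channel)
  ch <- resample_to_rate(ch, target_rate)
  highpass(magnitude(ch), cutoff = cutoff, order = order,
           zero_phase = zero_phase)
}
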