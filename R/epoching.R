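# Vocalisation-locked epoch extraction, envelope baseline correction,
# analytic envelope, and per-window median summaries.
#
# Epochs span [-3.5, +5] s around each vocalisation onset on a 60 Hz grid
# (511 samples; the onset sample is index 211, 1-based). Analysis windows:
# baseline [-2.5, -0.9) s, pre [-0.9, 0) s, during [0, 0.9) s; the
# [+3.5, +5] s tail is the reference span for envelope baseline correction.

#' Analysis window bounds
#'
#' @param base,pre,during,reference,epoch two-element numeric vectors,
#'   seconds relative to vocalisation onset. `base`, `pre`, `during` are
#'   half-open `[a, b)`; `reference` is the envelope baseline-correction
#'   span; `epoch` is the full extraction span.
#' @return a list of class `window_bounds`.
#' @export
window_bounds <- function(base = c(-2.5, -0.9), pre = c(-0.9, 0),
                          during = c(0, 0.9), reference = c(3.5, 5),
                          epoch = c(-3.5, 5)) {
  structure(list(base = base, pre = pre, during = during,
                 reference = reference, epoch = epoch),
            class = "window_bounds")
}

epoch_grid <- function(bounds = window_bounds(), rate = 60) {
  seq(bounds$epoch[1], bounds$epoch[2], by = 1 / rate)
}

in_window <- function(t_rel, win, closed = FALSE) {
  if (closed) t_rel >= win[1] - 1e-9 & t_rel <= win[2] + 1e-9
  else t_rel >= win[1] - 1e-9 & t_rel < win[2] - 1e-9
}

#' Extract vocalisation-locked epochs from a magnitude series
#'
#' One epoch per event. The onset is snapped to the nearest sample; epochs
#' running over the recording edge are excluded with reason `"edge"`, and
#' epochs whose span overlaps any masked (gap/artifact) sample with reason
#' `"artifact"`. With `exclude_overlap = TRUE`, epochs whose span contains
#' a following vocalisation onset are excluded with reason `"overlap"`.
#'
#' @param series a [magnitude_series()] on the session clock (post-sync).
#' @param events a [voc_events()] data frame.
#' @param bounds a [window_bounds()].
#' @param exclude_overlap exclude epochs containing the next event's onset.
#' @return a list of `epoch` objects (fields: `event_id`, `onset`,
#'   `placement`, `t_rel`, `raw`, `excluded`, `reason`).
#' @export
extract_epochs <- function(series, events, bounds = window_bounds(),
                           exclude_overlap = FALSE) {
  rate <- series$rate
  grid <- epoch_grid(bounds, rate)
  n_pre <- round(-bounds$epoch[1] * rate)    # samples before onset
  n_len <- length(grid)
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    onset <- events$onset[i]
    onset_idx <- which.min(abs(series$t - onset))
    lo <- onset_idx - n_pre
    hi <- lo + n_len - 1L
    ep <- list(event_id = i, onset = onset, placement = series$placement,
               t_rel = grid, raw = NULL, baselined = NULL, envelope = NULL,
               excluded = FALSE, reason = NA_character_)
    if (lo < 1L || hi > length(series$t) ||
        abs(series$t[onset_idx] - onset) > 0.5 / rate + 1e-9) {
      ep$excluded <- TRUE; ep$reason <- "edge"
    } else if (any(series$mask[lo:hi])) {
      ep$excluded <- TRUE; ep$reason <- "artifact"
      ep$raw <- series$value[lo:hi]
    } else {
      ep$raw <- series$value[lo:hi]
      if (exclude_overlap && i < nrow(events) &&
          events$onset[i + 1L] < onset + bounds$epoch[2]) {
        ep$excluded <- TRUE; ep$reason <- "overlap"
      }
    }
    out[[i]] <- structure(ep, class = "epoch")
  }
  if (!any(!vapply(out, function(e) e$excluded, logical(1))))
    warn_fmt("extract_epochs: no includable epochs (%d events)", nrow(events))
  out
}

#' @export
print.epoch <- function(x, ...) {
  cat(sprintf("<epoch> event %d @ %.2f s (%s)%s\n", x$event_id, x$onset,
              placement_id(x$placement),
              if (x$excluded) paste0(" EXCLUDED: ", x$reason) else ""))
  invisible(x)
}

# Upper/lower signal envelope by peak interpolation: cubic spline through
# local maxima (resp. minima), endpoints anchored. Falls back to the signal
# itself when fewer than two interior peaks exist (e.g. constant input).
peak_envelope <- function(x, min_sep = 2L, upper = TRUE) {
  v <- if (upper) x else -x
  pk <- find_peaks(v, min_sep = min_sep)
  pk <- union(union(1L, pk), length(x))
  pk <- sort(pk)
  if (length(pk) < 4L) return(x)
  env <- spline(pk, x[pk], xout = seq_along(x), method = "fmm")$y
  if (upper) pmax(env, x) else pmin(env, x)
}

#' Envelope baseline correction of an epoch
#'
#' Estimates the upper and lower peak-interpolated envelopes over the full
#' epoch, averages them, and subtracts the scalar mean of that midline over
#' the reference span (`[+3.5, +5]` s by default) from the whole segment.
#' This centres an oscillatory segment regardless of its offset.
#'
#' @param epoch an `epoch` from [extract_epochs()].
#' @param bounds a [window_bounds()] (for the reference span).
#' @param min_peak_sep minimum peak separation in samples for the envelope
#'   estimate.
#' @return the epoch with `baselined` filled in and `center` recorded.
#' @export
envelope_baseline_correct <- function(epoch, bounds = window_bounds(),
                                      min_peak_sep = 2L) {
  if (epoch$excluded) stop_fmt("envelope_baseline_correct: epoch is excluded")
  x <- epoch$raw
  up <- peak_envelope(x, min_peak_sep, upper = TRUE)
  lo <- peak_envelope(x, min_peak_sep, upper = FALSE)
  ref <- in_window(epoch$t_rel, bounds$reference, closed = TRUE)
  if (!any(ref))
    stop_fmt("envelope_baseline_correct: empty reference span")
  center <- mean((up[ref] + lo[ref]) / 2)
  epoch$baselined <- x - center
  epoch$center <- center
  epoch
}

# ---- 12-tap FIR analytic envelope -----------------------------------------

# Complex single-sideband FIR approximating the analytic-signal operator:
# least-squares fit of H(w) = exp(-i w alpha) over the positive passband
# and 0 over its mirror, with a small ridge for conditioning. The filter is
# linear-phase with group delay alpha = (n_taps - 1)/2 samples; the delay
# is compensated by interpolating the envelope back onto the input grid, so
# envelope timing is preserved.
design_analytic_fir <- function(n_taps = 12L, band = c(2, 10) / 30,
                                ridge = 1e-5) {
  alpha <- (n_taps - 1) / 2
  wp <- seq(band[1] * pi, band[2] * pi, length.out = 256L)
  w_all <- c(wp, -wp)
  tgt <- c(exp(-1i * wp * alpha), rep(0 + 0i, length(wp)))
  B <- vapply(0:(n_taps - 1L), function(n) exp(-1i * w_all * n),
              complex(length(w_all)))
  A <- cbind(rbind(Re(B), Im(B)), rbind(-Im(B), Re(B)))
  b <- c(Re(tgt), Im(tgt))
  M <- crossprod(A) + ridge * diag(ncol(A))
  p <- solve(M, crossprod(A, b))
  list(h = p[1:n_taps] + 1i * p[(n_taps + 1L):(2L * n_taps)], alpha = alpha)
}

.analytic_fir_cache <- new.env(parent = emptyenv())

analytic_fir <- function(n_taps = 12L) {
  key <- as.character(n_taps)
  if (is.null(.analytic_fir_cache[[key]]))
    .analytic_fir_cache[[key]] <- design_analytic_fir(n_taps)
  .analytic_fir_cache[[key]]
}

#' Analytic envelope via a 12-tap FIR filter
#'
#' Computes the modulus of the analytic signal approximated by a 12-tap
#' complex FIR filter; the filter's 5.5-sample group delay is compensated
#' so the envelope stays aligned with the input (phase-preserving). The
#' envelope is non-negative by construction.
#'
#' @param x a baselined `epoch` (operates on `$baselined`) or a numeric
#'   vector.
#' @param n_taps FIR length (default 12).
#' @return the epoch with `envelope` filled in, or a numeric vector.
#' @export
analytic_envelope <- function(x, n_taps = 12L) {
  if (inherits(x, "epoch")) {
    if (is.null(x$baselined))
      stop_fmt("analytic_envelope: run envelope_baseline_correct() first")
    x$envelope <- analytic_envelope(x$baselined, n_taps)
    return(x)
  }
  d <- analytic_fir(n_taps)
  h <- d$h
  n <- length(x)
  xp <- c(x, numeric(length(h)))
  re <- as.numeric(stats::filter(xp, Re(h), method = "convolution", sides = 1))
  im <- as.numeric(stats::filter(xp, Im(h), method = "convolution", sides = 1))
  keep <- !is.na(re)
  env_delayed <- 2 * sqrt(re[keep]^2 + im[keep]^2)
  approx(which(keep) - d$alpha, env_delayed, xout = seq_len(n), rule = 2)$y
}

#' Full-length FFT Hilbert envelope (reference implementation)
#'
#' Exact discrete analytic-signal modulus via the frequency-domain Hilbert
#' transform. Used as the independent oracle for [analytic_envelope()].
#'
#' @param x numeric vector.
#' @return non-negative envelope, same length.
#' @export
hilbert_envelope_fft <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Grand-average envelope across epochs
#'
#' Pointwise mean and standard error across included epochs on the common
#' epoch grid.
#'
#' @param epochs list of epochs with `envelope` present, or a numeric
#'   matrix (epochs in rows).
#' @return list with `t_rel`, `mean`, `se`, `n`.
#' @export
grand_average_envelope <- function(epochs) {
  if (is.matrix(epochs)) {
    m <- epochs
    t_rel <- seq_len(ncol(m))
  } else {
    keep <- !vapply(epochs, function(e) e$excluded, logical(1))
    epochs <- epochs[keep]
    if (length(epochs) < 2L)
      stop_fmt("grand_average_envelope: need at least 2 included epochs")
    m <- do.call(rbind, lapply(epochs, function(e)
      e$envelope %||% e$raw))
    t_rel <- epochs[[1]]$t_rel
  }
  if (nrow(m) < 2L)
    stop_fmt("grand_average_envelope: need at least 2 included epochs")
  mu <- colMeans(m)
  se <- apply(m, 2, sd) / sqrt(nrow(m))
  list(t_rel = t_rel, mean = mu, se = se, n = nrow(m))
}

#' Locate envelope inflection boundaries around onset
#'
#' Diagnostic reproduction of the rule that fixed the analysis windows at
#' +/- 0.9 s: on each side of the vocalisation onset, find the time of
#' maximum curvature change (largest absolute second difference) of the
#' smoothed mean envelope. The pipeline's analysis windows stay at the
#' fixed +/- 0.9 s; this operation is for QC plots only.
#'
#' @param t_rel epoch time grid, seconds.
#' @param mean_env mean envelope on that grid.
#' @param smooth_s moving-average smoothing window, seconds (default 0.1).
#' @param search search span on each side of onset, seconds; the region
#'   within `search[1]` of the onset is skipped so the onset transient
#'   itself is not reported.
#' @return list with `pre`, `post` (seconds; `NA` if not found) and `found`.
#' @export
locate_inflection <- function(t_rel, mean_env, smooth_s = 0.1,
                              search = c(0.2, 2.5)) {
  rate <- 1 / median(diff(t_rel))
  sm <- moving_average(mean_env, round(smooth_s * rate))
  d2 <- c(NA, diff(sm, differences = 2), NA)
  pick <- function(mask) {
    idx <- which(mask & is.finite(d2))
    if (!length(idx)) return(NA_real_)
    t_rel[idx[which.max(abs(d2[idx]))]]
  }
  post <- pick(t_rel >= search[1] & t_rel <= search[2])
  pre <- pick(t_rel <= -search[1] & t_rel >= -search[2])
  list(pre = pre, post = post, found = is.finite(pre) && is.finite(post))
}

#' Per-window median summaries
#'
#' For every event, limb and window: the median of the envelope samples in
#' the window is taken separately for the left and right sides, and the two
#' side medians are averaged into a single value (the model's dependent
#' measure). Events with one usable side contribute that side alone and are
#' flagged (`n_sides = 1`).
#'
#' @param epochs list of enveloped epochs across limbs/sides/events (e.g.
#'   the four infant channels of one session).
#' @param bounds a [window_bounds()].
#' @param infant_id,time_point identifiers attached to the output rows.
#' @param value which epoch trace to summarise (`"envelope"` default).
#' @return event-level rows: `infant_id`, `time_point`, `event_id`, `limb`,
#'   `window`, `median`, `n_sides`.
#' @export
window_medians <- function(epochs, bounds = window_bounds(),
                           infant_id = "unknown", time_point = NA_real_,
                           value = "envelope") {
  keep <- !vapply(epochs, function(e) e$excluded, logical(1))
  epochs <- epochs[keep]
  if (!length(epochs)) return(empty_summary_rows())
  meta <- data.frame(
    event_id = vapply(epochs, function(e) e$event_id, numeric(1)),
    limb = vapply(epochs, function(e) e$placement$limb, character(1)),
    side = vapply(epochs, function(e) e$placement$side, character(1)),
    stringsAsFactors = FALSE)
  wins <- c("base", "pre", "during")
  t_rel <- epochs[[1]]$t_rel
  win_idx <- lapply(wins, function(w) in_window(t_rel, bounds[[w]]))
  names(win_idx) <- wins
  rows <- list()
  for (ev in unique(meta$event_id)) {
    for (lb in unique(meta$limb[meta$event_id == ev])) {
      sel <- which(meta$event_id == ev & meta$limb == lb)
      for (w in wins) {
        side_med <- vapply(sel, function(j) {
          v <- epochs[[j]][[value]]
          if (is.null(v)) stop_fmt("window_medians: epochs lack '%s' values",
                                   value)
          median(v[win_idx[[w]]])
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          infant_id = infant_id, time_point = time_point, event_id = ev,
          limb = lb, window = w, median = mean(side_med),
          n_sides = length(side_med), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$n_sides < 2L))
    warn_fmt("window_medians: %d event-limb cell(s) had only one usable side",
             sum(out$n_sides < 2L & out$window == "base"))
  rownames(out) <- NULL
  out
}

empty_summary_rows <- function() {
  data.frame(infant_id = character(0), time_point = numeric(0),
             event_id = numeric(0), limb = character(0),
             window = character(0), median = numeric(0),
             n_sides = integer(0), stringsAsFactors = FALSE)
}

#' Baseline-corrected window differences
#'
#' Emits `diff_pre = pre - base` and `diff_during = during - base` per key
#' (infant, time point, event, limb). Keys lacking a `base` row are skipped
#' with a warning.
#'
#' @param rows event-level rows from [window_medians()].
#' @return rows with `window` in `diff_pre`, `diff_during`.
#' @export
baseline_diffs <- function(rows) {
  key <- interaction(rows$infant_id, rows$time_point, rows$event_id,
                     rows$limb, drop = TRUE)
  out <- list()
  skipped <- 0L
  for (k in levels(key)) {
    sub <- rows[key == k, , drop = FALSE]
    base <- sub$median[sub$window == "base"]
    if (!length(base)) { skipped <- skipped + 1L; next }
    for (w in c("pre", "during")) {
      v <- sub$median[sub$window == w]
      if (!length(v)) next
      r <- sub[sub$window == w, , drop = FALSE][1L, ]
      r$window <- paste0("diff_", w)
      r$median <- v - base
      out[[length(out) + 1L]] <- r
    }
  }
  if (skipped) warn_fmt("baseline_diffs: %d key(s) lacked a base row", skipped)
  res <- do.call(rbind, out) %||% empty_summary_rows()
  rownames(res) <- NULL
  res
}

#' Aggregate event-level rows per infant
#'
#' Mean of event medians per infant x time point x limb x window, with the
#' number of contributing events. Used for plots and descriptive tables;
#' models use the event-level rows.
#'
#' @param rows event-level rows from [window_medians()] or
#'   [baseline_diffs()].
#' @return aggregated rows with `median` (mean of event medians) and
#'   `n_events`.
#' @export
summarise_infant_windows <- function(rows) {
  agg <- aggregate(median ~ infant_id + time_point + limb + window,
                   data = rows, FUN = mean)
  n <- aggregate(median ~ infant_id + time_point + limb + window,
                 data = rows, FUN = length)
  agg$n_events <- n$median
  agg[order(agg$infant_id, agg$time_point, agg$limb, agg$window), ,
      drop = FALSE]
}
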