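# Small internal helpers shared across modules.

#' Centred moving average
#'
#' @param x numeric vector.
#' @param n window length in samples (coerced to an odd integer >= 1).
#' @return filtered vector, same length as `x`; ends use shrinking windows.
#' @keywords internal
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  if (n == 1L || length(x) < 2L) return(x)
  half <- (n - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Boolean run-length segments: start/end indices of TRUE runs.
true_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Dilate a logical mask by k samples on each side.
dilate_mask <- function(mask, k) {
  if (k <= 0 || !any(mask)) return(mask)
  runs <- true_runs(mask)
  out <- mask
  for (i in seq_len(nrow(runs))) {
    lo <- max(1L, runs$start[i] - k)
    hi <- min(length(mask), runs$end[i] + k)
    out[lo:hi] <- TRUE
  }
  out
}

# Local maxima of a vector with a minimum peak separation (samples).
# Returns indices sorted by position; among peaks closer than min_sep the
# larger one wins.
find_peaks <- function(x, min_sep = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(idx) < 2L || min_sep <= 1L) return(idx)
  ord <- idx[order(x[idx], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

# Parabolic interpolation of a peak at index i of y; returns fractional
# offset in (-0.5, 0.5) and interpolated height.
parabolic_peak <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(list(delta = 0, value = y[i]))
  a <- y[i - 1L]; b <- y[i]; c <- y[i + 1L]
  denom <- a - 2 * b + c
  if (abs(denom) < .Machine$double.eps) return(list(delta = 0, value = b))
  delta <- 0.5 * (a - c) / denom
  delta <- max(-0.5, min(0.5, delta))
  list(delta = delta, value = b - 0.25 * (a - c) * delta)
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 10007) %% 2147483629)
}

# Deterministic content hash (FNV-1a over the serialized object), hex string.
config_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
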