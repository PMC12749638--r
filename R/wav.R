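# Minimal RIFF/WAVE reader and writer.
#
# Only the subset of the format produced by field recorders is supported:
# canonical RIFF layout, PCM 16/24/32-bit integer or IEEE float 32/64-bit,
# any channel count (channels are averaged to mono on read).

#' Audio track container
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]`.
#' @param rate sampling rate in Hz.
#' @param t0 session-clock time of the first sample, seconds.
#' @return an object of class `audio_track`.
#' @export
audio_track <- function(samples, rate, t0 = 0) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop_fmt("audio_track: samples must be a non-empty numeric vector")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop_fmt("audio_track: rate must be a positive scalar")
  if (any(!is.finite(samples)))
    stop_fmt("audio_track: samples must be finite")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate),
                 t0 = as.numeric(t0)),
            class = "audio_track")
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf("<audio_track> %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate, x$t0))
  invisible(x)
}

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file (PCM 16/24/32-bit integer or IEEE float) and
#' returns a mono [audio_track()] with samples normalised to `[-1, 1]`.
#' Multi-channel files are averaged across channels.
#'
#' @param path path to a `.wav` file.
#' @return an [audio_track()] with `t0 = 0`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop_fmt("read_wav: file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop_fmt("read_wav: not a RIFF file: %s", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop_fmt("read_wav: not a WAVE file: %s", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(body[1:2], "integer", 1L, 2L, signed = FALSE,
                         endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, 2L, signed = FALSE,
                           endian = "little"),
        rate = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(body[15:16], "integer", 1L, 2L, signed = FALSE,
                       endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop_fmt("read_wav: missing fmt or data chunk in %s", path)

  bytes_per <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes_per
  if (fmt$format == 1L) {            # integer PCM
    if (fmt$bits == 16L) {
      vals <- readBin(data_raw, "integer", n_total, size = 2L,
                      signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 24L) {
      m <- matrix(as.integer(data_raw[seq_len(n_total * 3L)]),
                  nrow = 3L)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      vals <- v / 8388608
    } else if (fmt$bits == 32L) {
      vals <- readBin(data_raw, "integer", n_total, size = 4L,
                      endian = "little") / 2147483648
    } else {
      stop_fmt("read_wav: unsupported PCM bit depth %d in %s",
               fmt$bits, path)
    }
  } else if (fmt$format == 3L) {     # IEEE float
    vals <- readBin(data_raw, "double", n_total, size = bytes_per,
                    endian = "little")
  } else {
    stop_fmt("read_wav: unsupported (compressed?) format code %d in %s",
             fmt$format, path)
  }
  if (fmt$channels > 1L) {
    n_frames <- length(vals) %/% fmt$channels
    vals <- colMeans(matrix(vals[seq_len(n_frames * fmt$channels)],
                            nrow = fmt$channels))
  }
  audio_track(vals, fmt$rate, t0 = 0)
}

#' Write a WAV file
#'
#' Writes a mono PCM 16-bit WAV file. Samples outside `[-1, 1]` are clipped.
#'
#' @param track an [audio_track()], or a numeric vector (then `rate` is
#'   required).
#' @param path output path.
#' @param rate sampling rate in Hz, taken from `track` when it is an
#'   `audio_track`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(track, path, rate = NULL) {
  if (inherits(track, "audio_track")) {
    samples <- track$samples
    rate <- track$rate
  } else {
    samples <- as.numeric(track)
    if (is.null(rate)) stop_fmt("write_wav: rate required for raw samples")
  }
  x <- pmin(1, pmax(-1, samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")   # block align
  writeBin(16L, con, size = 2L, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
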