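# Accelerometer channels, session manifests and summary tables.
#
# The accelerometer file dialect is defined by this package (vendor
# containers are proprietary): comma-delimited UTF-8 text with header
# `time_s,acc_x,acc_y,acc_z`, time in seconds on the sensor clock and
# accelerations in m/s^2.

#' Sensor placement descriptor
#'
#' @param wearer `"infant"` or `"caregiver"`.
#' @param limb one of `"arm"`, `"leg"`, `"hand"` (caregiver hands are used
#'   for clock synchronisation only).
#' @param side `"left"` or `"right"`.
#' @return a named list of class `placement`.
#' @export
placement <- function(wearer, limb, side) {
  wearer <- match.arg(wearer, c("infant", "caregiver"))
  limb <- match.arg(limb, c("arm", "leg", "hand", "head", "torso"))
  side <- match.arg(side, c("left", "right", "centre"))
  structure(list(wearer = wearer, limb = limb, side = side),
            class = "placement")
}

placement_id <- function(p) paste(p$wearer, p$limb, p$side, sep = "_")

#' 3-axis accelerometer channel
#'
#' @param t sample times in seconds (strictly increasing).
#' @param x,y,z accelerations in m/s^2; may be `NA` where `gap_mask` is TRUE.
#' @param rate nominal sampling rate in Hz.
#' @param placement a [placement()].
#' @param gap_mask logical per sample; TRUE marks missing/interpolated data.
#' @return an object of class `acc_channel`.
#' @export
acc_channel <- function(t, x, y, z, rate, placement,
                        gap_mask = rep(FALSE, length(t))) {
  n <- length(t)
  if (!all(lengths(list(x, y, z, gap_mask)) == n))
    stop_fmt("acc_channel: t, x, y, z, gap_mask must have equal length")
  if (n > 1L && any(diff(t) <= 0))
    stop_fmt("acc_channel: time must be strictly increasing")
  ok <- !gap_mask
  if (any(!is.finite(x[ok])) || any(!is.finite(y[ok])) ||
      any(!is.finite(z[ok])))
    stop_fmt("acc_channel: non-finite values outside the gap mask")
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 z = as.numeric(z), rate = as.numeric(rate),
                 gap_mask = as.logical(gap_mask), placement = placement),
            class = "acc_channel")
}

#' @export
print.acc_channel <- function(x, ...) {
  cat(sprintf("<acc_channel> %s: %d samples @ %g Hz, %.1f%% gap\n",
              placement_id(x$placement), length(x$t), x$rate,
              100 * mean(x$gap_mask)))
  invisible(x)
}

#' Read an accelerometer table
#'
#' Reads the package's open accelerometer dialect and reconstructs dropped
#' packets: wherever consecutive timestamps are more than `1.5 /
#' nominal_rate` apart, the missing samples are re-inserted on the nominal
#' grid with `NA` values and `gap_mask = TRUE`. Rows with non-finite values
#' are also masked.
#'
#' @param path path to a CSV file with header `time_s,acc_x,acc_y,acc_z`.
#' @param placement a [placement()] attached to the channel.
#' @param nominal_rate nominal sampling rate in Hz (default 60).
#' @return an [acc_channel()].
#' @export
read_acc_table <- function(path, placement, nominal_rate = 60) {
  if (!file.exists(path)) stop_fmt("read_acc_table: file not found: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "acc_x", "acc_y", "acc_z")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop_fmt("read_acc_table: %s: missing column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  if (nrow(d) > 1L && any(diff(d$time_s) <= 0))
    stop_fmt("read_acc_table: %s: time_s is not strictly increasing", path)
  t <- d$time_s; x <- d$acc_x; y <- d$acc_y; z <- d$acc_z
  dt_nom <- 1 / nominal_rate
  gaps <- which(diff(t) > 1.5 * dt_nom)
  if (length(gaps)) {
    pieces_t <- list(); pieces_v <- list()
    prev <- 1L
    for (g in gaps) {
      n_missing <- round(diff(t)[g] / dt_nom) - 1L
      fill_t <- t[g] + dt_nom * seq_len(max(n_missing, 1L))
      fill_t <- fill_t[fill_t < t[g + 1L] - dt_nom / 2]
      pieces_t[[length(pieces_t) + 1L]] <- t[prev:g]
      pieces_v[[length(pieces_v) + 1L]] <-
        cbind(x[prev:g], y[prev:g], z[prev:g], FALSE)
      if (length(fill_t)) {
        pieces_t[[length(pieces_t) + 1L]] <- fill_t
        pieces_v[[length(pieces_v) + 1L]] <-
          cbind(NA_real_, NA_real_, NA_real_, TRUE)[rep(1L, length(fill_t)), ,
                                                    drop = FALSE]
      }
      prev <- g + 1L
    }
    pieces_t[[length(pieces_t) + 1L]] <- t[prev:length(t)]
    pieces_v[[length(pieces_v) + 1L]] <-
      cbind(x[prev:length(t)], y[prev:length(t)], z[prev:length(t)], FALSE)
    t <- unlist(pieces_t)
    vals <- do.call(rbind, pieces_v)
    x <- vals[, 1]; y <- vals[, 2]; z <- vals[, 3]
    mask <- as.logical(vals[, 4])
  } else {
    mask <- rep(FALSE, length(t))
  }
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(z)
  mask <- mask | bad
  acc_channel(t, x, y, z, rate = nominal_rate, placement = placement,
              gap_mask = mask)
}

#' Write an accelerometer table
#'
#' @param channel an [acc_channel()] (masked samples are written as gaps,
#'   i.e. their rows are omitted, matching how dropped packets appear in
#'   real recordings) or a data frame with the dialect's columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_acc_table <- function(channel, path) {
  if (inherits(channel, "acc_channel")) {
    keep <- !channel$gap_mask
    d <- data.frame(time_s = channel$t[keep], acc_x = channel$x[keep],
                    acc_y = channel$y[keep], acc_z = channel$z[keep])
  } else {
    d <- channel
  }
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Session manifest
#'
#' Describes one recording session: identifiers, file paths and the sensor
#' placement map. Head/torso sensors are accepted but not analysed;
#' caregiver entries must be hands (clock synchronisation only).
#'
#' @param infant_id opaque infant identifier.
#' @param time_point visit age in months; one of 4, 6, 9, 12.
#' @param audio_path,annotation_path paths to the session WAV and TextGrid.
#' @param sensors a list of `list(wearer=, limb=, side=, path=)` entries.
#' @param nominal_rate accelerometer nominal rate in Hz.
#' @return an object of class `session_manifest`.
#' @export
session_manifest <- function(infant_id, time_point, audio_path,
                             annotation_path, sensors, nominal_rate = 60) {
  if (!time_point %in% c(4, 6, 9, 12))
    stop_fmt("session_manifest: time_point must be one of 4, 6, 9, 12")
  pl <- lapply(sensors, function(s) placement(s$wearer, s$limb, s$side))
  for (p in pl) {
    if (p$wearer == "caregiver" && p$limb != "hand")
      stop_fmt("session_manifest: caregiver sensors are limited to hands")
  }
  infant_pl <- Filter(function(p) p$wearer == "infant" &&
                        p$limb %in% c("arm", "leg"), pl)
  combos <- unique(vapply(infant_pl, function(p) paste(p$limb, p$side),
                          character(1)))
  needed <- c("arm left", "arm right", "leg left", "leg right")
  if (!all(needed %in% combos))
    stop_fmt("session_manifest: infant sensors must cover all limb x side combinations (missing: %s)",
             paste(setdiff(needed, combos), collapse = ", "))
  structure(list(infant_id = as.character(infant_id),
                 time_point = as.numeric(time_point),
                 audio_path = audio_path, annotation_path = annotation_path,
                 sensors = sensors, nominal_rate = nominal_rate),
            class = "session_manifest")
}

#' Read / write a session manifest (YAML)
#' @param path YAML file path.
#' @return [session_manifest()] for the reader; `path` for the writer.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  session_manifest(m$infant_id, m$time_point, m$audio_path,
                   m$annotation_path, m$sensors,
                   m$nominal_rate %||% 60)
}

#' @rdname read_manifest
#' @param manifest a [session_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

summary_key_cols <- function(rows) {
  intersect(c("infant_id", "time_point", "event_id", "limb", "window"),
            names(rows))
}

#' Write a window-summary table (TSV)
#'
#' Long format, one row per key (infant x time point \[x event\] x limb x
#' window), stable column order; round-trips losslessly via
#' [read_summary_table()].
#'
#' @param rows summary rows as produced by [window_medians()] or
#'   [summarise_infant_windows()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(rows, path) {
  keys <- summary_key_cols(rows)
  if (!length(keys)) stop_fmt("write_summary_table: no key columns found")
  key_str <- do.call(paste, c(rows[keys], sep = "|"))
  dup <- duplicated(key_str)
  if (any(dup))
    stop_fmt("write_summary_table: duplicate key row(s): %s",
             paste(unique(key_str[dup]), collapse = "; "))
  ordered_cols <- c(keys, setdiff(names(rows), keys))
  write.table(rows[ordered_cols], path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_summary_table
#' @export
read_summary_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
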