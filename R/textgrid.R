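# Praat TextGrid interval-tier reader/writer (long and short text dialects).
#
# Utterance annotations are interval tiers: each labelled interval is one
# vocalisation event with an onset, an offset and a label. Empty or
# whitespace-only labels are separator intervals and are dropped on read.

#' Construct a table of vocalisation events
#'
#' @param onset,offset event boundaries in seconds (session clock).
#' @param label event labels; conventionally one of `protophone`,
#'   `syllable`, `word`, `other`.
#' @param coder annotator identifier.
#' @param validate check `offset > onset` and reject overlapping events.
#' @return a `data.frame` with columns `onset`, `offset`, `label`, `coder`,
#'   sorted by onset.
#' @export
voc_events <- function(onset, offset, label = "protophone", coder = "unknown",
                       validate = TRUE) {
  if (!length(onset))
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      label = character(0), coder = character(0),
                      stringsAsFactors = FALSE))
  d <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
                  label = as.character(label), coder = as.character(coder),
                  stringsAsFactors = FALSE)
  d <- d[order(d$onset), , drop = FALSE]
  rownames(d) <- NULL
  if (validate && nrow(d)) {
    if (any(d$offset <= d$onset))
      stop_fmt("voc_events: every offset must exceed its onset")
    if (nrow(d) > 1L && any(d$onset[-1L] < d$offset[-nrow(d)] - 1e-9))
      stop_fmt("voc_events: overlapping intervals in one tier are not allowed")
  }
  d
}

# Strip Praat string quoting.
tg_unquote <- function(s) {
  s <- sub('^\\s*"', "", s)
  s <- sub('"\\s*$', "", s)
  gsub('""', '"', s)
}

tg_num_after <- function(line) as.numeric(sub(".*=\\s*", "", line))

#' Read an interval tier from a Praat TextGrid
#'
#' Supports the long ("ooTextFile" with named fields) and short text
#' dialects. Intervals with empty or whitespace-only labels are dropped;
#' events are returned sorted by onset.
#'
#' @param path path to a `.TextGrid` file.
#' @param tier_name name of the interval tier to read.
#' @param coder value for the `coder` column (the format stores none).
#' @return a [voc_events()] data frame.
#' @export
read_textgrid <- function(path, tier_name = "vocalisations",
                          coder = "textgrid") {
  if (!file.exists(path)) stop_fmt("read_textgrid: file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 3L || !grepl("ooTextFile", lines[1]))
    stop_fmt("read_textgrid: %s line 1: not a text TextGrid (binary TextGrids are unsupported)",
             path)
  if (!grepl("TextGrid", lines[2]))
    stop_fmt("read_textgrid: %s line 2: object class is not TextGrid", path)
  long <- any(grepl("^\\s*item\\s*\\[", lines))
  tiers <- if (long) tg_parse_long(lines, path) else tg_parse_short(lines, path)
  names_avail <- vapply(tiers, function(t) t$name, character(1))
  hit <- which(names_avail == tier_name)
  if (!length(hit))
    stop_fmt("read_textgrid: tier '%s' not found in %s; available tiers: %s",
             tier_name, path,
             if (length(names_avail)) paste(names_avail, collapse = ", ")
             else "(none)")
  iv <- tiers[[hit[1L]]]$intervals
  keep <- !grepl("^\\s*$", iv$text)
  voc_events(iv$xmin[keep], iv$xmax[keep], iv$text[keep], coder = coder)
}

tg_parse_long <- function(lines, path) {
  item_at <- grep("^\\s*item\\s*\\[\\s*[0-9]+\\s*\\]", lines)
  tiers <- list()
  bounds <- c(item_at, length(lines) + 1L)
  for (k in seq_along(item_at)) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    cls_line <- grep("^\\s*class\\s*=", block, value = TRUE)
    if (!length(cls_line)) next
    if (!grepl("IntervalTier", cls_line[1])) next  # point tiers skipped
    name_line <- grep("^\\s*name\\s*=", block, value = TRUE)
    name <- tg_unquote(sub(".*=", "", name_line[1]))
    iv_at <- grep("^\\s*intervals\\s*\\[", block)
    xmin <- numeric(0); xmax <- numeric(0); text <- character(0)
    for (i in iv_at) {
      sub_block <- block[i:min(i + 4L, length(block))]
      mn <- grep("^\\s*xmin\\s*=", sub_block, value = TRUE)
      mx <- grep("^\\s*xmax\\s*=", sub_block, value = TRUE)
      tx <- grep("^\\s*text\\s*=", sub_block, value = TRUE)
      if (!length(mn) || !length(mx) || !length(tx))
        stop_fmt("read_textgrid: %s line %d: malformed interval block",
                 path, grep(block[i], lines, fixed = TRUE)[1])
      xmin <- c(xmin, tg_num_after(mn[1]))
      xmax <- c(xmax, tg_num_after(mx[1]))
      text <- c(text, tg_unquote(sub("[^=]*=", "", tx[1])))
    }
    tiers[[length(tiers) + 1L]] <-
      list(name = name,
           intervals = data.frame(xmin = xmin, xmax = xmax, text = text,
                                  stringsAsFactors = FALSE))
  }
  tiers
}

tg_parse_short <- function(lines, path) {
  # Short dialect: header (xmin, xmax, <exists>, size) then per tier:
  # "IntervalTier", "name", xmin, xmax, n, then n triples (xmin, xmax, text).
  body <- lines[-(1:2)]
  body <- body[!grepl("^\\s*$", body)]
  i <- 1L
  need <- function(k) {
    if (i + k - 1L > length(body))
      stop_fmt("read_textgrid: %s: truncated short-format file near line %d",
               path, i + 2L)
  }
  need(4L)
  i <- 3L                       # skip global xmin/xmax
  if (!grepl("exists", body[i]))
    stop_fmt("read_textgrid: %s line %d: expected <exists> flag", path, i + 2L)
  i <- i + 1L
  n_tiers <- as.integer(body[i]); i <- i + 1L
  tiers <- list()
  for (k in seq_len(n_tiers)) {
    need(5L)
    cls <- tg_unquote(body[i]); i <- i + 1L
    name <- tg_unquote(body[i]); i <- i + 1L
    i <- i + 2L                 # tier xmin/xmax
    n_iv <- as.integer(body[i]); i <- i + 1L
    if (is.na(n_iv))
      stop_fmt("read_textgrid: %s line %d: expected interval count", path,
               i + 1L)
    if (identical(cls, "IntervalTier")) {
      need(3L * n_iv)
      xmin <- numeric(n_iv); xmax <- numeric(n_iv); text <- character(n_iv)
      for (j in seq_len(n_iv)) {
        xmin[j] <- as.numeric(body[i]); i <- i + 1L
        xmax[j] <- as.numeric(body[i]); i <- i + 1L
        text[j] <- tg_unquote(body[i]); i <- i + 1L
      }
      tiers[[length(tiers) + 1L]] <-
        list(name = name,
             intervals = data.frame(xmin = xmin, xmax = xmax, text = text,
                                    stringsAsFactors = FALSE))
    } else {
      i <- i + 2L * n_iv        # point tier: (time, mark) pairs
    }
  }
  tiers
}

#' Write vocalisation events to a long-format TextGrid
#'
#' Gaps between events become empty separator intervals so that the tier
#' tiles `[0, xmax]` as Praat requires.
#'
#' @param events a [voc_events()] data frame.
#' @param path output path.
#' @param tier_name tier name to write.
#' @param xmax total duration of the annotated recording in seconds;
#'   defaults to the last offset.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(events, path, tier_name = "vocalisations",
                           xmax = NULL) {
  ev <- voc_events(events$onset, events$offset, events$label,
                   events$coder %||% "unknown")
  xmax <- xmax %||% if (nrow(ev)) max(ev$offset) else 1
  # tile [0, xmax] with alternating empty / labelled intervals
  iv_min <- numeric(0); iv_max <- numeric(0); iv_text <- character(0)
  cursor <- 0
  for (i in seq_len(nrow(ev))) {
    if (ev$onset[i] > cursor + 1e-9) {
      iv_min <- c(iv_min, cursor); iv_max <- c(iv_max, ev$onset[i])
      iv_text <- c(iv_text, "")
    }
    iv_min <- c(iv_min, ev$onset[i]); iv_max <- c(iv_max, ev$offset[i])
    iv_text <- c(iv_text, ev$label[i])
    cursor <- ev$offset[i]
  }
  if (cursor < xmax - 1e-9 || !length(iv_min)) {
    iv_min <- c(iv_min, cursor); iv_max <- c(iv_max, xmax)
    iv_text <- c(iv_text, "")
  }
  q <- function(s) paste0('"', gsub('"', '""', s), '"')
  out <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0 ",
    sprintf("xmax = %.10g ", xmax),
    "tiers? <exists> ",
    "size = 1 ",
    "item []: ",
    "    item [1]:",
    '        class = "IntervalTier" ',
    sprintf("        name = %s ", q(tier_name)),
    "        xmin = 0 ",
    sprintf("        xmax = %.10g ", xmax),
    sprintf("        intervals: size = %d ", length(iv_min)))
  for (i in seq_along(iv_min)) {
    out <- c(out,
             sprintf("        intervals [%d]:", i),
             sprintf("            xmin = %.10g ", iv_min[i]),
             sprintf("            xmax = %.10g ", iv_max[i]),
             sprintf("            text = %s ", q(iv_text[i])))
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
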