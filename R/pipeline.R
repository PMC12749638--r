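# End-to-end orchestration: manifest(s) -> sync -> preprocess -> epochs ->
# window medians -> model suite, with per-session failure isolation, a run
# manifest and array-level diagnostic figures.

#' Pipeline configuration
#'
#' @param sessions list of [session_manifest()]s, or paths to manifest
#'   YAML files.
#' @param bounds a [window_bounds()].
#' @param sync a [sync_config()].
#' @param highpass_cutoff,highpass_order,zero_phase magnitude-filter
#'   parameters.
#' @param artifact_threshold throw-artifact threshold in m/s^2, or `NULL`
#'   for the data-driven default (`median + 10 * MAD`).
#' @param exclude_overlap drop epochs containing a following onset.
#' @param tier_name annotation tier to read.
#' @param seed integer seed recorded in the run manifest.
#' @param out_dir output directory, or `NULL` to keep results in memory.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sessions, bounds = window_bounds(),
                            sync = sync_config(), highpass_cutoff = 1,
                            highpass_order = 2, zero_phase = TRUE,
                            artifact_threshold = NULL,
                            exclude_overlap = FALSE,
                            tier_name = "vocalisations", seed = 1,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

load_session_inputs <- function(ses, config) {
  if (is.character(ses)) ses <- read_manifest(ses)
  if (inherits(ses, "session_manifest")) {
    audio <- read_wav(ses$audio_path)
    events <- read_textgrid(ses$annotation_path, config$tier_name)
    channels <- lapply(ses$sensors, function(s)
      read_acc_table(s$path, placement(s$wearer, s$limb, s$side),
                     ses$nominal_rate))
    names(channels) <- vapply(channels, function(ch)
      placement_id(ch$placement), character(1))
    list(infant_id = ses$infant_id, time_point = ses$time_point,
         audio = audio, events = events, channels = channels)
  } else {
    ses  # in-memory session from simulate_cohort()
  }
}

#' Process one session
#'
#' Clap-sync the accelerometer clock to the audio clock, preprocess the
#' four infant channels to highpassed magnitude series with artifact
#' masks, extract vocalisation-locked epochs, baseline-correct, envelope,
#' and compute event-level window medians.
#'
#' @param ses a [session_manifest()], a path to one, or an in-memory
#'   session from [simulate_cohort()].
#' @param config a [pipeline_config()] (its `sessions` field is ignored
#'   here).
#' @return list with `rows` (event-level medians + baseline diffs), `qc`
#'   (lag, claps, masked fraction, epoch exclusions), and `epochs`.
#' @export
process_session <- function(ses, config = pipeline_config(list())) {
  dat <- load_session_inputs(ses, config)
  hands <- Filter(function(ch) ch$placement$wearer == "caregiver" &&
                    ch$placement$limb == "hand", dat$channels)
  claps <- detect_claps(dat$audio, config$sync)
  lag <- estimate_lag(dat$audio, hands, config$sync)
  infant <- Filter(function(ch) ch$placement$wearer == "infant" &&
                     ch$placement$limb %in% c("arm", "leg"), dat$channels)
  infant <- apply_lag(infant, lag$lag)
  epochs <- list()
  masked_frac <- numeric(0)
  for (ch in infant) {
    series <- preprocess_channel(ch, cutoff = config$highpass_cutoff,
                                 order = config$highpass_order,
                                 zero_phase = config$zero_phase)
    art <- detect_artifacts(series, threshold = config$artifact_threshold)
    series$mask <- series$mask | as.logical(art)
    masked_frac[placement_id(ch$placement)] <- mean(series$mask)
    eps <- extract_epochs(series, dat$events, config$bounds,
                          exclude_overlap = config$exclude_overlap)
    eps <- lapply(eps, function(e) {
      if (e$excluded) return(e)
      analytic_envelope(envelope_baseline_correct(e, config$bounds))
    })
    epochs <- c(epochs, eps)
  }
  rows <- window_medians(epochs, config$bounds, infant_id = dat$infant_id,
                         time_point = dat$time_point)
  rows <- rbind(rows, baseline_diffs(rows))
  excl <- table(vapply(epochs, function(e)
    if (e$excluded) e$reason else "included", character(1)))
  list(rows = rows,
       qc = list(infant_id = dat$infant_id, time_point = dat$time_point,
                 lag = lag$lag, peak_corr = lag$peak_corr,
                 n_claps = nrow(claps), masked_frac = masked_frac,
                 epochs = as.list(excl)),
       epochs = epochs)
}

#' Run the full pipeline over a cohort
#'
#' Processes every session (failures are isolated, logged and summarised),
#' pools event-level rows, writes the summary TSV and run manifest when
#' `out_dir` is set, and runs the model suite.
#'
#' @param config a [pipeline_config()] whose `sessions` lists the cohort.
#' @param keep_epochs retain per-session epochs in the result (memory-heavy).
#' @return list of class `pipeline_result`: `rows`, `report`
#'   ([run_full_suite()] output, `NULL` if too few sessions succeeded),
#'   `qc`, `failures`, `run_manifest`.
#' @export
run_pipeline <- function(config, keep_epochs = FALSE) {
  rows <- list()
  qc <- list()
  failures <- list()
  epochs <- list()
  for (i in seq_along(config$sessions)) {
    res <- tryCatch(process_session(config$sessions[[i]], config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(session = i, message = conditionMessage(res))
      next
    }
    rows[[length(rows) + 1L]] <- res$rows
    qc[[length(qc) + 1L]] <- res$qc
    if (keep_epochs) epochs[[length(epochs) + 1L]] <- res$epochs
  }
  all_rows <- do.call(rbind, rows) %||% empty_summary_rows()
  report <- NULL
  if (length(unique(all_rows$infant_id)) >= 2L)
    report <- tryCatch(run_full_suite(all_rows), error = function(e) {
      failures[[length(failures) + 1L]] <<-
        list(session = NA, message = conditionMessage(e))
      NULL
    })
  run_manifest <- list(
    package_version = as.character(packageVersion("vocmotor")),
    seed = config$seed, config_hash = config_hash(config),
    n_sessions = length(config$sessions), n_failed = length(failures),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (nrow(all_rows))
      write_summary_table(all_rows,
                          file.path(config$out_dir, "window_medians.tsv"))
    jsonlite::write_json(list(run = run_manifest, qc = qc,
                              failures = failures),
                         file.path(config$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(rows = all_rows, report = report, qc = qc,
                 failures = failures, run_manifest = run_manifest,
                 epochs = if (keep_epochs) epochs else NULL),
            class = "pipeline_result")
}

utils::globalVariables(c("t_rel", "se"))

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d rows, %d session failure(s)\n",
              nrow(x$rows), length(x$failures)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Envelope and window-summary diagnostic panels
#'
#' Per time point: the grand-average envelope (mean +/- SE) for arms and
#' legs over the epoch span with the three analysis windows shaded, and
#' boxplots of per-infant window means. The plotted arrays are returned so
#' checks can run on numbers rather than pixels; figures are written only
#' when `out_dir` is set.
#'
#' @param epochs list of enveloped epochs (with `infant_id`/`time_point`
#'   metadata attached by the caller) or a list of per-time-point epoch
#'   lists.
#' @param rows event-level summary rows.
#' @param bounds a [window_bounds()].
#' @param out_dir directory for PDF output, or `NULL`.
#' @return list with `curves` (per time point x limb: `t_rel`, `mean`,
#'   `se`) and `box_data` (per-infant window means), invisibly plottable.
#' @export
plot_envelope_panels <- function(epochs, rows, bounds = window_bounds(),
                                 out_dir = NULL) {
  if (!length(epochs) || !nrow(rows)) {
    warn_fmt("plot_envelope_panels: empty input; nothing plotted")
    return(invisible(list(curves = list(), box_data = NULL)))
  }
  flat <- if (inherits(epochs[[1]], "epoch")) epochs else unlist(epochs,
                                                                recursive = FALSE)
  keep <- !vapply(flat, function(e) e$excluded, logical(1))
  flat <- flat[keep]
  limb_of <- vapply(flat, function(e) e$placement$limb, character(1))
  curves <- list()
  for (lb in unique(limb_of)) {
    sub <- flat[limb_of == lb]
    if (length(sub) < 2L) next
    ga <- grand_average_envelope(sub)
    curves[[lb]] <- ga
  }
  box_data <- summarise_infant_windows(rows[rows$window %in%
                                              c("base", "pre", "during"), ])
  if (!is.null(out_dir) && length(curves)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cdat <- do.call(rbind, lapply(names(curves), function(lb)
      data.frame(limb = lb, t_rel = curves[[lb]]$t_rel,
                 mean = curves[[lb]]$mean, se = curves[[lb]]$se)))
    p1 <- ggplot2::ggplot(cdat, ggplot2::aes(x = t_rel, y = mean)) +
      ggplot2::annotate("rect", xmin = bounds$base[1], xmax = bounds$base[2],
                        ymin = -Inf, ymax = Inf, alpha = 0.15,
                        fill = "steelblue") +
      ggplot2::annotate("rect", xmin = bounds$pre[1], xmax = bounds$pre[2],
                        ymin = -Inf, ymax = Inf, alpha = 0.15,
                        fill = "goldenrod") +
      ggplot2::annotate("rect", xmin = bounds$during[1],
                        xmax = bounds$during[2], ymin = -Inf, ymax = Inf,
                        alpha = 0.15, fill = "darkcyan") +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - se, ymax = mean + se),
                           fill = "grey70", alpha = 0.6) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~limb, ncol = 1) +
      ggplot2::labs(x = "time from vocalisation onset [s]",
                    y = "envelope [m/s²]")
    ggplot2::ggsave(file.path(out_dir, "envelope_panels.pdf"), p1,
                    width = 7, height = 5)
    p2 <- ggplot2::ggplot(box_data,
                          ggplot2::aes(x = factor(window,
                                                  c("base", "pre", "during")),
                                       y = median)) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_grid(limb ~ time_point) +
      ggplot2::labs(x = "window", y = "per-infant mean of event medians")
    ggplot2::ggsave(file.path(out_dir, "window_boxplots.pdf"), p2,
                    width = 8, height = 5)
  }
  invisible(list(curves = curves, box_data = box_data))
}
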