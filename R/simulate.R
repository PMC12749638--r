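# Synthetic dyad-session generator.
#
# Generates complete infant-caregiver sessions (audio, utterance
# annotations, accelerometer channels) and whole longitudinal cohorts with
# known ground truth, reproducing the statistical structure the analysis
# assumes: a window effect (base < pre < during), per-time-point limb
# differences with a developmental crossover, per-infant random intercepts
# and limb slopes, audio-IMU clock lag with a five-clap synchronisation
# event, dropped packets, 60 -> 40 Hz rate-drop segments and brief
# high-amplitude throw artifacts.

tp_levels <- c(4, 6, 9, 12)

#' Default per-window envelope increments
#'
#' Additive envelope increments (m/s^2) applied over the pre (`[-0.9, 0)`
#' s) and during (`[0, 0.9)` s) windows of each vocalisation, by time point
#' and limb. Defaults reproduce the published coupling pattern: grand
#' window increments of +0.21 (pre) and +0.31 (during) m/s^2 over baseline,
#' with small per-time-point leg-arm asymmetries (legs slightly higher at 4
#' and 6 months, arms at 9 and 12 months).
#'
#' @param pre_mean,during_mean grand increments, m/s^2.
#' @param pre_leg_minus_arm,during_leg_minus_arm leg-arm asymmetry of the
#'   increment per time point (4, 6, 9, 12 months).
#' @return list of two 4 x 2 matrices (`pre`, `during`), rows = time
#'   points, columns = `arm`, `leg`.
#' @export
default_coupling_delta <- function(pre_mean = 0.21, during_mean = 0.31,
                                   pre_leg_minus_arm = c(0.06, 0.13, -0.04, -0.03),
                                   during_leg_minus_arm = c(0.12, 0.23, -0.04, -0.09)) {
  mk <- function(mu, d) {
    m <- cbind(arm = mu - d / 2, leg = mu + d / 2)
    rownames(m) <- as.character(tp_levels)
    m
  }
  list(pre = mk(pre_mean, pre_leg_minus_arm),
       during = mk(during_mean, during_leg_minus_arm))
}

#' Default baseline envelope levels
#'
#' Resting limb-acceleration envelope (m/s^2) per time point and limb. The
#' grand level is an order-of-magnitude choice (no physical-unit baseline
#' is published); the leg-arm differences follow the published baseline
#' pattern: comparable limbs at 4 and 6 months, arms above legs at 9 and
#' 12 months.
#'
#' @param level grand baseline level, m/s^2.
#' @param leg_minus_arm leg-arm baseline difference per time point.
#' @return 4 x 2 matrix, rows = time points, columns = `arm`, `leg`.
#' @export
default_baseline_level <- function(level = 1.5,
                                   leg_minus_arm = c(0.00, 0.14, -0.39, -0.25)) {
  m <- cbind(arm = level - leg_minus_arm / 2, leg = level + leg_minus_arm / 2)
  rownames(m) <- as.character(tp_levels)
  m
}

#' Simulation configuration
#'
#' All durations in seconds, rates in Hz, accelerations in m/s^2.
#'
#' @param n_infants number of infants in a cohort.
#' @param timepoints visit ages in months, a subset of `c(4, 6, 9, 12)`.
#' @param session_duration session length (default 313 s).
#' @param voc_rate vocalisation rate, events per minute.
#' @param refractory minimum inter-onset interval, seconds.
#' @param dur_logmean,dur_logsd lognormal utterance-duration parameters
#'   (defaults give mean 0.593 s, sd 0.5 s).
#' @param baseline_level 4 x 2 matrix from [default_baseline_level()], or a
#'   scalar applied to all cells.
#' @param coupling_delta list of `pre`/`during` 4 x 2 matrices from
#'   [default_coupling_delta()], or `NULL` for zero coupling.
#' @param sd_intercept,sd_slope_limb,corr_int_slope per-infant random
#'   intercept sd, limb-slope sd and their correlation.
#' @param sd_resid residual (per event x limb x window) envelope sd.
#' @param carrier_type `"noise"` (band-limited Gaussian, default) or
#'   `"tone"` (deterministic sinusoid; use with `sd_resid = 0` for exact
#'   calibration checks).
#' @param carrier_band carrier frequency band, Hz.
#' @param tone_freq tone carrier frequency, Hz.
#' @param lag_audio_imu injected clock lag: accelerometer clock behind
#'   audio by this many seconds.
#' @param n_claps,clap_start,clap_spacing synchronisation clap burst.
#' @param audio_rate audio sampling rate.
#' @param acc_rate accelerometer nominal rate.
#' @param p_gap per-channel probability of a dropped-packet gap.
#' @param gap_len gap length, seconds.
#' @param p_rate_drop per-channel probability of a 60 -> 40 Hz segment.
#' @param rate_drop_len rate-drop segment length, seconds.
#' @param p_artifact per-channel probability of a throw artifact.
#' @param artifact_amp,artifact_len_range artifact amplitude and length
#'   range (the published artifacts are brief, up to 0.6 s).
#' @param attrition probability that a visit is missing entirely
#'   (missing-at-random; default 0.13, matching the published 41/318
#'   excluded visits).
#' @param noise_floor audio background amplitude.
#' @param voc_amp,clap_amp vocalisation and clap audio amplitudes.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_infants = 10,
                       timepoints = c(4, 6, 9, 12),
                       session_duration = 313,
                       voc_rate = 6,
                       refractory = 0.5,
                       dur_logmean = -0.7912,
                       dur_logsd = 0.7329,
                       baseline_level = default_baseline_level(),
                       coupling_delta = default_coupling_delta(),
                       sd_intercept = 0.3,
                       sd_slope_limb = 0.2,
                       corr_int_slope = 0.2,
                       sd_resid = 1.2,
                       carrier_type = c("noise", "tone"),
                       carrier_band = c(2, 8),
                       tone_freq = 5,
                       lag_audio_imu = 0.35,
                       n_claps = 5,
                       clap_start = 3,
                       clap_spacing = 0.7,
                       audio_rate = 44100,
                       acc_rate = 60,
                       p_gap = 0.1,
                       gap_len = 0.5,
                       p_rate_drop = 0.1,
                       rate_drop_len = 5,
                       p_artifact = 0.1,
                       artifact_amp = 50,
                       artifact_len_range = c(0.1, 0.6),
                       attrition = 0.13,
                       noise_floor = 0.002,
                       voc_amp = 0.15,
                       clap_amp = 0.9) {
  carrier_type <- match.arg(carrier_type)
  if (is.null(coupling_delta))
    coupling_delta <- default_coupling_delta(0, 0, rep(0, 4), rep(0, 4))
  if (length(baseline_level) == 1L)
    baseline_level <- default_baseline_level(baseline_level, rep(0, 4))
  stopifnot(sd_intercept >= 0, sd_slope_limb >= 0, sd_resid >= 0,
            abs(corr_int_slope) <= 1, voc_rate > 0, refractory >= 0,
            all(timepoints %in% tp_levels))
  structure(as.list(environment()), class = "sim_config")
}

#' Expected cell means implied by a configuration
#'
#' The envelope median the generator injects for every time point x limb x
#' window cell (random effects and residuals excluded).
#'
#' @param config a [sim_config()].
#' @return data frame with `time_point`, `limb`, `window`, `mean`.
#' @export
sim_cell_means <- function(config) {
  g <- expand.grid(time_point = tp_levels, limb = c("arm", "leg"),
                   window = c("base", "pre", "during"),
                   stringsAsFactors = FALSE)
  g$mean <- mapply(function(tp, lb, w) {
    base <- config$baseline_level[as.character(tp), lb]
    if (w == "base") base
    else base + config$coupling_delta[[w]][as.character(tp), lb]
  }, g$time_point, g$limb, g$window)
  g
}

#' Simulate a vocalisation train
#'
#' Onsets follow a homogeneous Poisson process at `voc_rate` per minute,
#' thinned so consecutive kept onsets are at least `refractory` seconds
#' apart; durations are lognormal. Onsets start after the clap burst
#' (claps precede the interaction) and events that would run past the
#' session end are dropped.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a [voc_events()] data frame.
#' @export
simulate_voc_train <- function(config, seed = 1) {
  set.seed(seed)
  dur <- config$session_duration
  t_min <- min(config$clap_start + config$n_claps * config$clap_spacing + 1,
               dur)
  n <- if (dur - t_min <= 0) 0L
       else rpois(1, config$voc_rate / 60 * (dur - t_min))
  onsets <- sort(runif(n, t_min, dur))
  kept <- numeric(0)
  last <- -Inf
  for (o in onsets) {
    if (o - last >= config$refractory) { kept <- c(kept, o); last <- o }
  }
  lens <- rlnorm(length(kept), config$dur_logmean, config$dur_logsd)
  if (length(kept) > 1L) {
    # utterances are produced on separate expirations: clip each duration
    # to just before the next onset so intervals never overlap
    max_len <- c(diff(kept) - 0.05, Inf)
    lens <- pmin(lens, max_len)
  }
  ok <- kept + lens <= dur & lens > 0.02
  if (!any(ok)) {
    if (length(kept))
      warn_fmt("simulate_voc_train: no events fit in the session; returning best effort")
    return(voc_events(numeric(0), numeric(0), character(0)))
  }
  labels <- sample(c("protophone", "syllable", "word"),
                   sum(ok), replace = TRUE, prob = c(0.7, 0.25, 0.05))
  voc_events(kept[ok], (kept + lens)[ok], labels, coder = "sim")
}

#' Synthesise session audio
#'
#' Background noise floor, a band-limited noise burst with a smooth (Hann)
#' amplitude envelope over each vocalisation interval, and a sharp
#' high-amplitude transient at each clap time.
#'
#' @param events a [voc_events()] data frame.
#' @param clap_times clap times in seconds (audio clock).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return an [audio_track()] at `config$audio_rate`.
#' @export
synth_audio <- function(events, clap_times, config, seed = 1) {
  set.seed(seed)
  fs <- config$audio_rate
  n <- round(config$session_duration * fs)
  x <- rnorm(n, 0, config$noise_floor)
  tt <- (seq_len(n) - 1L) / fs
  for (i in seq_len(nrow(events))) {
    idx <- which(tt >= events$onset[i] & tt < events$offset[i])
    if (!length(idx)) next
    env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = length(idx))))
    x[idx] <- x[idx] + config$voc_amp * env * rnorm(length(idx))
  }
  for (tc in clap_times) {
    idx <- which(abs(tt - tc) < 0.04)
    if (!length(idx)) next
    shape <- exp(-(tt[idx] - tc)^2 / (2 * 0.008^2))
    x[idx] <- x[idx] + config$clap_amp * shape * sign(rnorm(length(idx), 0.5))
  }
  audio_track(pmin(1, pmax(-1, x)), fs)
}

clap_times <- function(config) {
  config$clap_start + config$clap_spacing * (seq_len(config$n_claps) - 1L)
}

#' Draw per-infant random effects
#'
#' Bivariate normal intercept/limb-slope pairs with the configured sds and
#' correlation.
#'
#' @param n number of infants.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data frame with `infant_id`, `b_intercept`, `b_limb`.
#' @export
draw_infant_effects <- function(n, config, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  rho <- config$corr_int_slope
  b0 <- config$sd_intercept * z1
  b1 <- config$sd_slope_limb * (rho * z1 + sqrt(1 - rho^2) * z2)
  data.frame(infant_id = sprintf("inf%03d", seq_len(n)),
             b_intercept = b0, b_limb = b1, stringsAsFactors = FALSE)
}

# Band-limited Gaussian noise carrier on grid tt, normalised so the median
# of its exact analytic envelope is 1 (window medians of a modulated
# carrier then recover the modulation level).
noise_carrier <- function(n, rate, band) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(seq(0, floor(n / 2)), -seq(ceiling(n / 2) - 1, 1)) * rate / n
  X[abs(f) < band[1] | abs(f) > band[2]] <- 0
  x <- Re(fft(X, inverse = TRUE) / n)
  env <- hilbert_envelope_fft(x)
  x / median(env)
}

# Session-clock envelope for one infant limb: baseline + random effects +
# event-window increments + per-event-window residuals, floored at a small
# positive level.
limb_envelope <- function(tt, events, tp, limb, effects, eps, config) {
  base <- config$baseline_level[as.character(tp), limb]
  e <- rep(base + effects$b_intercept + effects$b_limb * (limb == "leg"),
           length(tt))
  bounds <- window_bounds()
  for (i in seq_len(nrow(events))) {
    on <- events$onset[i]
    for (w in c("base", "pre", "during")) {
      span <- bounds[[w]] + on
      idx <- tt >= span[1] & tt < span[2]
      if (!any(idx)) next
      inc <- eps[i, limb, w]
      if (w != "base")
        inc <- inc + config$coupling_delta[[w]][as.character(tp), limb]
      e[idx] <- e[idx] + inc
    }
  }
  pmax(e, 0.05)
}

#' Synthesise accelerometer channels for one session
#'
#' Produces the four infant channels (arm/leg x left/right) and two
#' caregiver hand channels. Infant channels carry a band-limited
#' oscillatory carrier amplitude-modulated to the injected envelope plus
#' gravity along the sensor x axis; caregiver hands carry sharp clap
#' transients. All accelerometer timestamps are shifted by
#' `-lag_audio_imu` relative to the audio clock (the sensor clock runs
#' behind). Dropped-packet gaps, 60 -> 40 Hz rate-drop segments and brief
#' throw artifacts are injected per configuration.
#'
#' @param events a [voc_events()] data frame (audio clock).
#' @param infant_effects one row of [draw_infant_effects()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param time_point visit age in months.
#' @return list with `channels` (list of [acc_channel()]) and `truth`
#'   (injected lag, per-event residuals, artifact and gap spans).
#' @export
synth_acc <- function(events, infant_effects, config, seed = 1,
                      time_point = 4) {
  set.seed(seed)
  fs <- config$acc_rate
  lag <- config$lag_audio_imu
  dur <- config$session_duration
  tt <- seq(0, dur, by = 1 / fs)           # audio clock
  n <- length(tt)
  wins <- c("base", "pre", "during")
  eps <- array(rnorm(nrow(events) * 2 * 3, 0, config$sd_resid),
               dim = c(max(nrow(events), 1L), 2, 3),
               dimnames = list(NULL, c("arm", "leg"), wins))
  if (config$sd_resid == 0) eps[] <- 0
  channels <- list()
  truth <- list(lag = lag, eps = eps, artifacts = list(), gaps = list(),
                rate_drops = list(), effects = infant_effects)
  for (limb in c("arm", "leg")) {
    env <- limb_envelope(tt, events, time_point, limb, infant_effects,
                         eps, config)
    for (side in c("left", "right")) {
      carrier <- switch(config$carrier_type,
        noise = noise_carrier(n, fs, config$carrier_band),
        tone = cos(2 * pi * config$tone_freq * tt +
                     runif(1, 0, 2 * pi) * (config$sd_resid > 0)))
      s <- env * carrier
      s <- pmax(pmin(s, 9), -9)
      pl <- placement("infant", limb, side)
      ch <- inject_channel_defects(tt - lag, 9.81 + s, fs, pl, config,
                                   truth_env = environment())
      channels[[placement_id(pl)]] <- ch
    }
  }
  # head and torso sensors: low-level background motion only (worn but not
  # analysed downstream)
  for (limb in c("head", "torso")) {
    pl <- placement("infant", limb, "centre")
    s <- 0.3 * noise_carrier(n, fs, config$carrier_band)
    channels[[placement_id(pl)]] <-
      acc_channel(tt - lag, 9.81 + s, rnorm(n, 0, 0.02), rnorm(n, 0, 0.02),
                  fs, pl)
  }
  for (side in c("left", "right")) {
    s <- 0.2 * noise_carrier(n, fs, c(1, 10))
    for (tc in clap_times(config))
      s <- s + 40 * exp(-(tt - tc)^2 / (2 * 0.03^2))
    pl <- placement("caregiver", "hand", side)
    channels[[placement_id(pl)]] <-
      acc_channel(tt - lag, 9.81 + s, rnorm(n, 0, 0.05), rnorm(n, 0, 0.05),
                  fs, pl)
  }
  list(channels = channels, truth = truth)
}

# Apply rate-drop / gap / artifact defects to one infant channel.
# `truth_env` is the synth_acc frame whose `truth` list is updated.
inject_channel_defects <- function(t, x, fs, pl, config, truth_env) {
  id <- placement_id(pl)
  dur <- t[length(t)] - t[1]
  long_enough <- dur > 35
  # throw artifact: brief high-amplitude burst added to the signal
  if (long_enough && runif(1) < config$p_artifact) {
    len <- runif(1, config$artifact_len_range[1], config$artifact_len_range[2])
    at <- runif(1, t[1] + 10, t[length(t)] - 10)
    idx <- t >= at & t < at + len
    x[idx] <- x[idx] + config$artifact_amp * sin(2 * pi * 15 * (t[idx] - at))
    truth_env$truth$artifacts[[id]] <- c(at, at + len)
  }
  # 60 -> 40 Hz rate-drop segment: resample a span onto a 1/40 s grid
  if (long_enough && runif(1) < config$p_rate_drop) {
    at <- runif(1, t[1] + 15, t[length(t)] - 15 - config$rate_drop_len)
    seg <- t >= at & t < at + config$rate_drop_len
    if (any(seg)) {
      t40 <- seq(min(t[seg]), max(t[seg]), by = 1 / 40)
      x40 <- spline(t, x, xout = t40, method = "fmm")$y
      keep <- !seg
      ord <- order(c(t[keep], t40))
      t <- c(t[keep], t40)[ord]
      x <- c(x[keep], x40)[ord]
      truth_env$truth$rate_drops[[id]] <- c(at, at + config$rate_drop_len)
    }
  }
  mask <- rep(FALSE, length(t))
  # dropped-packet gap
  if (long_enough && runif(1) < config$p_gap) {
    at <- runif(1, t[1] + 10, t[length(t)] - 10)
    idx <- t >= at & t < at + config$gap_len
    mask[idx] <- TRUE
    x[idx] <- NA_real_
    truth_env$truth$gaps[[id]] <- c(at, at + config$gap_len)
  }
  acc_channel(t, x, rnorm(length(t), 0, 0.02), rnorm(length(t), 0, 0.02),
              fs, pl, gap_mask = mask)
}

#' Simulate a longitudinal cohort of sessions
#'
#' One session per infant x time point (minus missing-at-random visits at
#' the configured attrition rate). With `dir` set, each session's WAV,
#' TextGrid, accelerometer CSVs and YAML manifest are written to disk
#' together with a `truth.json`; otherwise everything stays in memory.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param dir output directory, or `NULL` for in-memory sessions.
#' @return list with `sessions` (each: `infant_id`, `time_point`,
#'   `events`, `audio`, `channels`, `truth`, and paths when written) and
#'   `truth` (cohort-level: infant effects, config, seed).
#' @export
simulate_cohort <- function(config, seed = 1, dir = NULL) {
  effects <- draw_infant_effects(config$n_infants, config,
                                 child_seed(seed, 0))
  set.seed(child_seed(seed, 1))
  visit_present <- matrix(runif(config$n_infants * length(config$timepoints)) >=
                            config$attrition,
                          nrow = config$n_infants)
  sessions <- list()
  k <- 0L
  for (i in seq_len(config$n_infants)) {
    for (j in seq_along(config$timepoints)) {
      if (!visit_present[i, j]) next
      k <- k + 1L
      tp <- config$timepoints[j]
      s_seed <- child_seed(seed, 100L + 7L * k)
      events <- simulate_voc_train(config, s_seed)
      audio <- synth_audio(events, clap_times(config), config, s_seed + 1L)
      acc <- synth_acc(events, effects[i, ], config, s_seed + 2L,
                       time_point = tp)
      ses <- list(infant_id = effects$infant_id[i], time_point = tp,
                  events = events, audio = audio,
                  channels = acc$channels, truth = acc$truth)
      if (!is.null(dir)) ses <- write_session(ses, config, dir)
      sessions[[k]] <- ses
    }
  }
  truth <- list(effects = effects, seed = seed,
                cell_means = sim_cell_means(config),
                config_hash = config_hash(config))
  if (!is.null(dir)) {
    jsonlite::write_json(
      list(effects = effects, seed = seed,
           cell_means = sim_cell_means(config)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(sessions = sessions, truth = truth)
}

write_session <- function(ses, config, dir) {
  base <- file.path(dir, sprintf("%s_t%02d", ses$infant_id, ses$time_point))
  dir.create(base, recursive = TRUE, showWarnings = FALSE)
  audio_path <- file.path(base, "audio.wav")
  write_wav(ses$audio, audio_path)
  ann_path <- file.path(base, "vocalisations.TextGrid")
  write_textgrid(ses$events, ann_path, xmax = config$session_duration)
  sensors <- list()
  for (id in names(ses$channels)) {
    ch <- ses$channels[[id]]
    p <- file.path(base, paste0(id, ".csv"))
    write_acc_table(ch, p)
    sensors[[length(sensors) + 1L]] <-
      list(wearer = ch$placement$wearer, limb = ch$placement$limb,
           side = ch$placement$side, path = p)
  }
  manifest <- session_manifest(ses$infant_id, ses$time_point, audio_path,
                               ann_path, sensors, config$acc_rate)
  man_path <- file.path(base, "manifest.yaml")
  write_manifest(manifest, man_path)
  ses$manifest <- manifest
  ses$manifest_path <- man_path
  ses
}

#' Simulate event-level summary rows directly from the model
#'
#' Bypasses the signal chain and draws the dependent measure (per event x
#' limb x window median acceleration) straight from the assumed
#' mixed-model structure: cell mean + per-infant random intercept +
#' per-infant limb slope + Gaussian residual. This is the generator used
#' for power, type-I-error and coverage studies, where hundreds of cohorts
#' are needed.
#'
#' @param config a [sim_config()]; `n_infants`, `timepoints`,
#'   `events_per_visit`, random-effect and residual parameters are used.
#' @param events_per_visit events per infant visit.
#' @param seed integer seed.
#' @return event-level rows as from [window_medians()].
#' @export
simulate_rows <- function(config, events_per_visit = 30, seed = 1) {
  effects <- draw_infant_effects(config$n_infants, config,
                                 child_seed(seed, 0))
  set.seed(child_seed(seed, 2))
  cells <- sim_cell_means(config)
  key <- function(tp, lb, w) cells$mean[cells$time_point == tp &
                                          cells$limb == lb & cells$window == w]
  g <- expand.grid(event_id = seq_len(events_per_visit),
                   limb = c("arm", "leg"),
                   window = c("base", "pre", "during"),
                   time_point = config$timepoints,
                   infant = seq_len(config$n_infants),
                   stringsAsFactors = FALSE)
  mu <- mapply(key, g$time_point, g$limb, g$window)
  b0 <- effects$b_intercept[g$infant]
  b1 <- effects$b_limb[g$infant] * (g$limb == "leg")
  # the residual is shared between the two (averaged) sides, one draw per
  # event x limb x window
  res <- rnorm(nrow(g), 0, config$sd_resid)
  data.frame(infant_id = effects$infant_id[g$infant],
             time_point = g$time_point, event_id = g$event_id,
             limb = g$limb, window = g$window,
             median = mu + b0 + b1 + res, n_sides = 2L,
             stringsAsFactors = FALSE)
}
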