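# The dyad-session generator: vocalisation trains, audio, accelerometer
# channels, cohorts and ground truth.

test_that("vocalisation trains follow the thinned Poisson model", {
  cfg <- sim_config(session_duration = 313, voc_rate = 6, attrition = 0)
  counts <- vapply(1:200, function(s)
    nrow(simulate_voc_train(cfg, s)), numeric(1))
  # mean count sits inside the central 95% band of Poisson(rate * duration)
  lam <- 6 / 60 * 313
  expect_gte(mean(counts), qpois(0.025, lam))
  expect_lte(mean(counts), qpois(0.975, lam))

  # a 5 s refractory constraint is respected exactly
  cfg5 <- sim_config(refractory = 5)
  ev <- simulate_voc_train(cfg5, 7)
  expect_true(all(diff(ev$onset) >= 5))

  # determinism
  expect_identical(simulate_voc_train(cfg, 9), simulate_voc_train(cfg, 9))

  # durations match the configured lognormal location (grand mean ~0.59 s)
  durs <- unlist(lapply(1:50, function(s) {
    e <- simulate_voc_train(cfg, s); e$offset - e$onset
  }))
  expect_gt(mean(durs), 0.4)
  expect_lt(mean(durs), 0.8)
})

test_that("synthetic audio has bursts at events and transients at claps", {
  cfg <- quick_cfg()
  none <- voc_events(numeric(0), numeric(0), character(0))

  # no events, no claps: nothing crosses the clap detection threshold
  quiet <- synth_audio(none, numeric(0), cfg, 1)
  expect_error(detect_claps(quiet), "expected 5 claps")

  # five claps at known times appear as local envelope maxima within 5 ms
  tc <- vocmotor:::clap_times(cfg)
  clappy <- synth_audio(none, tc, cfg, 2)
  claps <- detect_claps(clappy)
  expect_equal(nrow(claps), 5)
  expect_lt(max(vapply(tc, function(x) min(abs(claps$time - x)),
                       numeric(1))), 0.005)

  # a vocalisation raises in-event RMS at least 10x over silence
  ev <- voc_events(10, 10.6)
  aud <- synth_audio(ev, numeric(0), cfg, 3)
  tt <- (seq_along(aud$samples) - 1) / aud$rate
  rms <- function(idx) sqrt(mean(aud$samples[idx]^2))
  expect_gt(rms(tt >= 10 & tt < 10.6) / rms(tt >= 8 & tt < 9), 10)
})

test_that("zero-coupling channels have event-locked flat envelopes", {
  cfg <- quick_cfg(session_duration = 313, voc_rate = 20,
                   coupling_delta = NULL, sd_resid = 0.3, lag_audio_imu = 0)
  ev <- simulate_voc_train(cfg, 21)
  acc <- synth_acc(ev, draw_infant_effects(1, cfg, 21)[1, ], cfg, 21, 6)
  series <- preprocess_channel(acc$channels[["infant_arm_left"]])
  eps <- extract_epochs(series, ev)
  eps <- lapply(eps, function(e) {
    if (e$excluded) e else analytic_envelope(envelope_baseline_correct(e))
  })
  suppressWarnings(rows <- window_medians(eps, infant_id = "a",
                                          time_point = 6))
  d <- baseline_diffs(rows)
  dd <- d$median[d$window == "diff_during"]
  expect_gt(length(dd), 50)
  se <- sd(dd) / sqrt(length(dd))
  expect_lt(abs(mean(dd)), 3 * se + 0.01)
})

test_that("a noise-free during-window step is reproduced exactly", {
  delta <- default_coupling_delta(0, 0.5, rep(0, 4), rep(0, 4))
  cfg <- clean_cfg(session_duration = 120, coupling_delta = delta)
  ev <- simulate_voc_train(cfg, 31)
  acc <- synth_acc(ev, draw_infant_effects(1, cfg, 31)[1, ], cfg, 31, 6)
  series <- preprocess_channel(acc$channels[["infant_leg_left"]])
  eps <- extract_epochs(series, ev)
  e <- Filter(function(x) !x$excluded, eps)[[1]]
  e <- analytic_envelope(envelope_baseline_correct(e))
  b <- median(e$envelope[vocmotor:::in_window(e$t_rel, c(-2.5, -0.9))])
  d <- median(e$envelope[vocmotor:::in_window(e$t_rel, c(0, 0.9))])
  expect_equal(d - b, 0.5, tolerance = 0.05)
})

test_that("random effects match the configured covariance at n = 2000", {
  cfg <- sim_config(sd_intercept = 0.3, sd_slope_limb = 0.2,
                    corr_int_slope = 0.2)
  eff <- draw_infant_effects(2000, cfg, 5)
  expect_equal(sd(eff$b_intercept), 0.3, tolerance = 0.03)
  expect_equal(sd(eff$b_limb), 0.2, tolerance = 0.02)
  expect_equal(cor(eff$b_intercept, eff$b_limb), 0.2, tolerance = 0.07)
})

test_that("cohorts have the expected session and channel structure", {
  cfg <- sim_config(n_infants = 5, timepoints = c(4, 6, 9, 12),
                    session_duration = 15, voc_rate = 20, attrition = 0,
                    p_gap = 0, p_rate_drop = 0, p_artifact = 0)
  coh <- simulate_cohort(cfg, seed = 2)
  expect_equal(length(coh$sessions), 20)
  for (ses in coh$sessions) {
    wearers <- vapply(ses$channels, function(ch) ch$placement$wearer,
                      character(1))
    expect_equal(sum(wearers == "infant"), 6)
    expect_equal(sum(wearers == "caregiver"), 2)
  }
  # determinism: identical (config, seed) gives identical events and signals
  coh2 <- simulate_cohort(cfg, seed = 2)
  expect_identical(coh$sessions[[3]]$events, coh2$sessions[[3]]$events)
  expect_identical(coh$sessions[[3]]$channels[["infant_arm_left"]]$x,
                   coh2$sessions[[3]]$channels[["infant_arm_left"]]$x)
  expect_identical(coh$truth$effects, coh2$truth$effects)
})

test_that("attrition removes whole visits at the configured rate", {
  cfg <- sim_config(n_infants = 40, timepoints = c(4, 6, 9, 12),
                    session_duration = 5, voc_rate = 30, attrition = 0.5)
  coh <- simulate_cohort(cfg, seed = 3)
  n <- length(coh$sessions)
  expect_gt(n, qbinom(0.001, 160, 0.5))
  expect_lt(n, qbinom(0.999, 160, 0.5))
})

test_that("written cohorts produce the complete io file set", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_infants = 1, timepoints = 4, session_duration = 10,
                    voc_rate = 30, attrition = 0)
  coh <- simulate_cohort(cfg, seed = 4, dir = dir)
  ses <- coh$sessions[[1]]
  expect_true(file.exists(ses$manifest_path))
  expect_true(file.exists(file.path(dir, "truth.json")))
  m <- read_manifest(ses$manifest_path)
  expect_true(file.exists(m$audio_path))
  expect_true(file.exists(m$annotation_path))
  expect_equal(length(m$sensors), 8)
  ev <- read_textgrid(m$annotation_path)
  expect_equal(nrow(ev), nrow(ses$events))
})

test_that("model-level rows reproduce the configured cell means", {
  cfg <- sim_config(n_infants = 200, sd_resid = 0.5)
  rows <- simulate_rows(cfg, events_per_visit = 10, seed = 6)
  cm <- sim_cell_means(cfg)
  for (k in sample(nrow(cm), 6)) {
    got <- mean(rows$median[rows$time_point == cm$time_point[k] &
                              rows$limb == cm$limb[k] &
                              rows$window == cm$window[k]])
    se <- 0.6 / sqrt(200 * 10)   # generous bound incl. random effects
    expect_lt(abs(got - cm$mean[k]), 5 * se + 0.05)
  }
  expect_identical(simulate_rows(cfg, 10, 6), rows)
})
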