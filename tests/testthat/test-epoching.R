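# Epoch extraction, envelope baseline correction, analytic envelope,
# grand averages, window medians and baseline differences.

pl <- placement("infant", "arm", "left")

series_of <- function(v, t0 = 0, mask = rep(FALSE, length(v))) {
  magnitude_series(t0 + (seq_along(v) - 1) / 60, v, 60, pl, mask)
}

test_that("epoch grid and half-open window sample counts are fixed", {
  g <- vocmotor:::epoch_grid()
  expect_equal(length(g), 511)
  expect_equal(which(abs(g) < 1e-9), 211)   # onset sample
  b <- window_bounds()
  expect_equal(sum(vocmotor:::in_window(g, b$base)), 96)
  expect_equal(sum(vocmotor:::in_window(g, b$pre)), 54)
  expect_equal(sum(vocmotor:::in_window(g, b$during)), 54)
})

test_that("extract_epochs applies edge, artifact and overlap rules", {
  v <- rnorm(20 * 60)
  s <- series_of(v)
  ev <- voc_events(c(1, 10), c(1.4, 10.4))
  eps <- extract_epochs(s, ev)
  expect_true(eps[[1]]$excluded)            # needs -3.5 s of history
  expect_equal(eps[[1]]$reason, "edge")
  expect_false(eps[[2]]$excluded)
  expect_equal(length(eps[[2]]$raw), 511)

  # epoch overlapping a masked sample is excluded
  mask <- rep(FALSE, length(v)); mask[12 * 60] <- TRUE
  s2 <- series_of(v, mask = mask)
  expect_warning(eps2 <- extract_epochs(s2, ev), "no includable")
  expect_true(eps2[[2]]$excluded)
  expect_equal(eps2[[2]]$reason, "artifact")

  # optional exclusion of epochs containing the next onset
  s3 <- series_of(rnorm(40 * 60))
  ev3 <- voc_events(c(10, 12), c(10.4, 12.4))
  eps3 <- extract_epochs(s3, ev3, exclude_overlap = TRUE)
  expect_true(eps3[[1]]$excluded)
  expect_equal(eps3[[1]]$reason, "overlap")
  eps3b <- extract_epochs(s3, ev3, exclude_overlap = FALSE)
  expect_false(eps3b[[1]]$excluded)
})

test_that("envelope baseline correction centres epochs", {
  # constant epoch: upper = lower = value, centred to exactly zero
  e <- envelope_baseline_correct(make_epoch(rep(2, 511)))
  expect_equal(e$center, 2)
  expect_true(all(abs(e$baselined) < 1e-12))

  # sinusoid about an offset: centre recovers the offset
  m <- 3; A <- 1.5
  x <- m + A * sin(2 * pi * 5 * epoch_t)
  e2 <- envelope_baseline_correct(make_epoch(x))
  # discrete peak sampling at 12 samples/cycle limits centre precision
  expect_lt(abs(e2$center - m), 0.03 * A)
  tail_mean <- mean(e2$baselined[epoch_t >= 3.5])
  expect_lt(abs(tail_mean), 0.02 * A)

  # shift invariance: adding a constant does not change the output
  e3 <- envelope_baseline_correct(make_epoch(x + 7))
  expect_equal(e3$baselined, e2$baselined, tolerance = 1e-9)
})

test_that("envelope baseline correction is idempotent", {
  set.seed(41)
  x <- 2 + cumsum(rnorm(511, 0, 0.1)) + sin(2 * pi * 4 * epoch_t)
  e1 <- envelope_baseline_correct(make_epoch(x))
  e2 <- envelope_baseline_correct(make_epoch(e1$baselined))
  expect_lt(abs(e2$center), 1e-6 + 0.001 * diff(range(x)))
})

test_that("the 12-tap analytic envelope matches the full Hilbert oracle", {
  # zero in, zero out
  expect_equal(analytic_envelope(rep(0, 511)), rep(0, 511))

  mid <- 60:450
  # 5 Hz tone of amplitude 2: mid-epoch envelope within 5 % of 2
  x <- 2 * cos(2 * pi * 5 * epoch_t)
  env <- analytic_envelope(x)
  expect_lt(max(abs(env[mid] - 2)) / 2, 0.05)
  oracle <- hilbert_envelope_fft(x)
  expect_lt(max(abs(env[mid] - oracle[mid])) / 2, 0.05)

  # AM burst: envelope peak within 2 samples of the true peak
  true_env <- exp(-(epoch_t - 1)^2 / (2 * 0.4^2))
  xa <- true_env * cos(2 * pi * 6 * epoch_t)
  ea <- analytic_envelope(xa)
  expect_lte(abs(which.max(ea) - which.max(true_env)), 2)

  # epoch method fills the envelope slot and it is non-negative
  e <- analytic_envelope(envelope_baseline_correct(make_epoch(x + 5)))
  expect_true(all(e$envelope >= 0))
  expect_lt(max(abs(e$envelope[mid] - 2)) / 2, 0.06)
})

test_that("grand averages have closed-form mean and SE", {
  a <- make_env_epoch(rep(0, 511))
  b <- make_env_epoch(rep(2, 511))
  ga <- grand_average_envelope(list(a, b))
  expect_equal(ga$mean, rep(1, 511))
  expect_equal(ga$se, rep(1, 511))

  same <- replicate(5, make_env_epoch(sin(epoch_t)), simplify = FALSE)
  ga2 <- grand_average_envelope(same)
  expect_equal(ga2$mean, sin(epoch_t))
  expect_equal(max(ga2$se), 0)

  expect_error(grand_average_envelope(list(a)), "at least 2")
})

test_that("the grand average concentrates on the population curve", {
  set.seed(42)
  truth <- 1 + 0.5 * exp(-(epoch_t)^2 / 0.5)
  eps <- lapply(1:200, function(i)
    make_env_epoch(truth + rnorm(511, 0, 0.3)))
  ga <- grand_average_envelope(eps)
  ok <- abs(ga$mean - truth) < 3 * ga$se
  expect_gte(mean(ok), 0.99)
})

test_that("locate_inflection finds curvature-change boundaries", {
  # piecewise-linear ramp with a knee at +0.9 s
  ramp <- pmin(pmax(epoch_t, 0), 0.9)
  li <- locate_inflection(epoch_t, ramp, smooth_s = 0)
  expect_lt(abs(li$post - 0.9), 1.5 / 60)

  # symmetric tent: boundaries symmetric within one sample
  tent <- pmax(0, 1.5 - abs(epoch_t))
  li2 <- locate_inflection(epoch_t, tent, smooth_s = 0)
  expect_lt(abs(li2$post + li2$pre), 1.5 / 60)

  # simulated vocalisation envelope: post boundary in a plausible range
  cfg <- quick_cfg(session_duration = 120)
  ev <- simulate_voc_train(cfg, 5)
  aud <- synth_audio(ev, vocmotor:::clap_times(cfg), cfg, 5)
  ea <- vocmotor:::audio_envelope_at(aud, 60)
  curves <- lapply(seq_len(nrow(ev)), function(i) {
    idx <- which.min(abs(ea$t - ev$onset[i]))
    if (idx - 210 < 1 || idx + 300 > length(ea$value)) return(NULL)
    ea$value[(idx - 210):(idx + 300)]
  })
  m <- colMeans(do.call(rbind, Filter(Negate(is.null), curves)))
  li3 <- locate_inflection(epoch_t, m)
  expect_true(li3$found)
  expect_gte(li3$post, 0.2)
  expect_lte(li3$post, 2.0)
})

test_that("window medians average sides and match a sort-based oracle", {
  # both sides constant per window
  stepped <- function(vals) {
    v <- numeric(511)
    v[vocmotor:::in_window(epoch_t, c(-3.5, -0.9))] <- vals[1]
    v[vocmotor:::in_window(epoch_t, c(-0.9, 0))] <- vals[2]
    v[vocmotor:::in_window(epoch_t, c(0, 5.001))] <- vals[3]
    v
  }
  eps <- list(make_env_epoch(stepped(c(1, 2, 3)), side = "left"),
              make_env_epoch(stepped(c(1, 2, 3)), side = "right"))
  rows <- window_medians(eps, infant_id = "a", time_point = 4)
  expect_equal(rows$median[match(c("base", "pre", "during"), rows$window)],
               c(1, 2, 3))

  # left = 1, right = 3 everywhere -> averaged value 2
  eps2 <- list(make_env_epoch(rep(1, 511), side = "left"),
               make_env_epoch(rep(3, 511), side = "right"))
  rows2 <- window_medians(eps2, infant_id = "a", time_point = 4)
  expect_true(all(rows2$median == 2))
  expect_true(all(rows2$n_sides == 2))

  # random epochs against an explicit sort-based median + mean oracle
  set.seed(43)
  L <- rnorm(511); R <- rnorm(511)
  rows3 <- window_medians(list(make_env_epoch(L, side = "left"),
                               make_env_epoch(R, side = "right")),
                          infant_id = "a", time_point = 4)
  sort_med <- function(v) {
    s <- sort(v); n <- length(s)
    if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  for (w in c("base", "pre", "during")) {
    idx <- vocmotor:::in_window(epoch_t, window_bounds()[[w]])
    expect_equal(rows3$median[rows3$window == w],
                 (sort_med(L[idx]) + sort_med(R[idx])) / 2)
  }
})

test_that("window medians are symmetric in sides and scale-equivariant", {
  set.seed(44)
  L <- abs(rnorm(511)); R <- abs(rnorm(511))
  mk <- function(l, r) list(make_env_epoch(l, side = "left"),
                            make_env_epoch(r, side = "right"))
  a <- window_medians(mk(L, R), infant_id = "a", time_point = 4)
  b <- window_medians(mk(R, L), infant_id = "a", time_point = 4)
  expect_equal(a$median, b$median)

  sc <- window_medians(mk(3 * L, 3 * R), infant_id = "a", time_point = 4)
  expect_equal(sc$median, 3 * a$median, tolerance = 1e-12)
})

test_that("one-sided events contribute the available side with a flag", {
  eps <- list(make_env_epoch(rep(4, 511), side = "left"))
  expect_warning(rows <- window_medians(eps, infant_id = "a",
                                        time_point = 4), "one usable side")
  expect_true(all(rows$median == 4))
  expect_true(all(rows$n_sides == 1))
})

test_that("baseline differences subtract the base window per key", {
  rows <- data.frame(infant_id = "a", time_point = 4, event_id = 1,
                     limb = "arm", window = c("base", "pre", "during"),
                     median = c(1, 2, 3), n_sides = 2L,
                     stringsAsFactors = FALSE)
  d <- baseline_diffs(rows)
  expect_equal(d$median[d$window == "diff_pre"], 1)
  expect_equal(d$median[d$window == "diff_during"], 2)

  rows$median <- c(1, 1, 3)   # pre equals base
  expect_equal(baseline_diffs(rows)$median[1], 0)

  # missing base -> skipped with warning
  expect_warning(out <- baseline_diffs(rows[rows$window != "base", ]),
                 "lacked a base")
  expect_equal(nrow(out), 0)
})

test_that("noise-free simulated epochs recover injected medians to <1%", {
  cfg <- clean_cfg(session_duration = 120)
  ev <- simulate_voc_train(cfg, 3)
  acc <- synth_acc(ev, draw_infant_effects(1, cfg, 4)[1, ], cfg, 5, 6)
  eps <- list()
  for (id in c("infant_arm_left", "infant_arm_right",
               "infant_leg_left", "infant_leg_right")) {
    series <- preprocess_channel(acc$channels[[id]])
    e <- extract_epochs(series, ev)
    eps <- c(eps, lapply(e, function(ep) {
      if (ep$excluded) ep
      else analytic_envelope(envelope_baseline_correct(ep))
    }))
  }
  rows <- window_medians(eps, infant_id = "x", time_point = 6)
  cm <- sim_cell_means(cfg)
  for (lb in c("arm", "leg")) for (w in c("base", "pre", "during")) {
    truth <- cm$mean[cm$time_point == 6 & cm$limb == lb & cm$window == w]
    got <- median(rows$median[rows$limb == lb & rows$window == w])
    expect_lt(abs(got - truth) / truth, 0.01)
  }
  # and the baseline differences recover the injected increments
  d <- baseline_diffs(rows)
  for (lb in c("arm", "leg")) for (w in c("pre", "during")) {
    inj <- cfg$coupling_delta[[w]]["6", lb]
    got <- median(d$median[d$limb == lb & d$window == paste0("diff_", w)])
    expect_lt(abs(got - inj), 0.05)
  }
})
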