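# Mixed-model fitting, model comparison, Type-II ANOVA, random-effect
# tests, EMM contrasts and R-squared.

rows_cfg <- function(...) {
  args <- modifyList(list(n_infants = 20, attrition = 0), list(...))
  do.call(sim_config, args)
}

test_that("fit_model matches OLS when random variances are zero", {
  cfg <- rows_cfg(sd_intercept = 0, sd_slope_limb = 0, corr_int_slope = 0,
                  sd_resid = 0.5)
  rows <- simulate_rows(cfg, events_per_visit = 6, seed = 51)
  fit <- suppressWarnings(
    fit_model(model_spec("median", "full", "slope", "REML"), rows))
  d <- vocmotor:::spec_rows(model_spec("median", "full", "slope"), rows)
  ols <- lm(median ~ Time_Window * Time_Point * Limb, data = d)
  b_mix <- lme4::fixef(fit$fit)
  b_ols <- coef(ols)
  expect_equal(unname(b_mix), unname(b_ols[names(b_mix)]),
               tolerance = 1e-4)
})

test_that("refitting identical data reproduces the likelihood", {
  cfg <- rows_cfg()
  rows <- simulate_rows(cfg, events_per_visit = 4, seed = 52)
  spec <- model_spec("median", "window_by_timepoint", "slope", "ML")
  f1 <- fit_model(spec, rows)
  f2 <- fit_model(spec, rows)
  expect_lt(abs(f1$logLik - f2$logLik), 1e-8)
  expect_true(f1$converged)
})

test_that("information-criterion identities hold for every fit", {
  cfg <- rows_cfg(n_infants = 12)
  rows <- simulate_rows(cfg, events_per_visit = 3, seed = 53)
  rows <- rbind(rows, baseline_diffs(rows))
  specs <- list(model_spec("median", "full", "slope", "ML"),
                model_spec("median", "window_by_timepoint", "intercept"),
                model_spec("median_pre", "timepoint_by_limb", "slope"),
                model_spec("diff_during", "timepoint_by_limb", "intercept"))
  for (sp in specs) {
    f <- fit_model(sp, rows)
    expect_lt(abs(f$AIC - aic_from(f$logLik, f$n_params)), 1e-6)
    expect_lt(abs(f$BIC - (f$n_params * log(f$n_obs) - 2 * f$logLik)), 1e-6)
  }
})

test_that("model comparison computes LRTs for nested pairs only", {
  cfg <- rows_cfg(n_infants = 12)
  rows <- simulate_rows(cfg, events_per_visit = 3, seed = 54)
  full <- fit_model(model_spec("median", "full", "slope", "ML"), rows)
  red <- fit_model(model_spec("median", "two_way", "slope", "ML"), rows)
  cmp <- compare_models(list(full = full, reduced = red),
                        lrt_pairs = list(c("full", "reduced")))
  expect_equal(nrow(cmp$table), 2)
  expect_gte(cmp$lrt$LRT, 0)            # nested ML likelihoods are ordered
  expect_equal(cmp$lrt$df, full$n_params - red$n_params)

  # identical models give LRT 0, p 1
  same <- compare_models(list(a = full, b = full))
  expect_equal(same$table$logLik[1], same$table$logLik[2])
  expect_error(compare_models(list(a = red, b = full),
                              lrt_pairs = list(c("a", "b"))),
               "full-vs-reduced")
})

test_that("printed-table arithmetic is reproduced by the IC helpers", {
  # log-likelihoods and parameter counts as printed in the reference
  # model-comparison table
  expect_equal(lrt_stat(-83907.41, -85744.69), 3674.56, tolerance = 0.05)
  expect_equal(aic_from(-83907.41, 16), 167846.81, tolerance = 0.05)
})

test_that("Type-II Satterthwaite ANOVA matches classical ANOVA at variance 0", {
  set.seed(55)
  # balanced one-factor layout, no infant variance
  d <- expand.grid(infant_id = sprintf("i%02d", 1:16),
                   time_point = c(4, 6, 9, 12), event_id = 1:5,
                   limb = "arm", window = "during",
                   stringsAsFactors = FALSE)
  d$median <- 1 + 0.2 * (d$time_point == 9) + rnorm(nrow(d), 0, 0.4)
  # remove all between-infant variation so the variance estimate is at the
  # boundary and the mixed F reduces to the classical one
  inf_mean <- ave(d$median, d$infant_id)
  d$median <- d$median - inf_mean + mean(d$median)
  fit <- fit_model(model_spec("median_during", "Time_Point", "intercept"),
                   d)
  a <- anova_typeII(fit)
  dd <- vocmotor:::factorise_rows(d)
  cls <- anova(lm(median ~ Time_Point, data = dd))
  expect_equal(a$F[a$term == "Time_Point"], cls$`F value`[1],
               tolerance = 1e-3)
  expect_equal(a$NumDF[1], 3)

  # effect-size conventions
  expect_equal(a$cohens_f, sqrt(a$NumDF * a$F / a$DenDF))
  expect_equal(a$partial_eta2,
               a$NumDF * a$F / (a$NumDF * a$F + a$DenDF))
  f2 <- a$cohens_f^2
  expect_equal(f2, a$partial_eta2 / (1 - a$partial_eta2), tolerance = 1e-9)
})

test_that("effect sizes from F are zero at F = 0", {
  expect_equal(cohens_f_from_F(0, 3, 100), 0)
  expect_equal(partial_eta2_from_F(0, 3, 100), 0)
})

test_that("ANOVA results are invariant to factor level relabelling", {
  cfg <- rows_cfg(n_infants = 14)
  rows <- simulate_rows(cfg, events_per_visit = 3, seed = 56)
  fit <- fit_model(model_spec("median", "window_by_timepoint", "slope"),
                   rows)
  a1 <- anova_typeII(fit)
  rows2 <- rows
  rows2$window <- factor(rows2$window, levels = c("during", "base", "pre"))
  rows2$window <- as.character(rows2$window)
  # reorder rows too, so the data frame ordering differs
  rows2 <- rows2[order(rows2$window, rows2$infant_id), ]
  fit2 <- fit_model(model_spec("median", "window_by_timepoint", "slope"),
                    rows2)
  a2 <- anova_typeII(fit2)
  expect_equal(a1$F, a2$F[match(a1$term, a2$term)], tolerance = 1e-4)
  expect_equal(a1$p, a2$p[match(a1$term, a2$term)], tolerance = 1e-4)
})

test_that("random-intercept LRT is conservative under the null and powerful otherwise", {
  null_rej <- 0L
  alt_rej <- 0L
  n_null <- 120L
  n_alt <- 40L
  for (r in seq_len(n_null)) {
    cfg <- rows_cfg(n_infants = 10, sd_intercept = 0, sd_slope_limb = 0,
                    sd_resid = 0.5)
    rows <- simulate_rows(cfg, events_per_visit = 2, seed = 500 + r)
    rows <- rows[rows$window == "during", ]
    fw <- suppressWarnings(
      fit_model(model_spec("median_during", "timepoint_by_limb",
                           "intercept", "REML"), rows))
    fo <- fit_model(model_spec("median_during", "timepoint_by_limb",
                               "none", "REML"), rows)
    lrt <- ranova_random(fw, fo)
    if (is.finite(lrt$p) && lrt$p < 0.05) null_rej <- null_rej + 1L
  }
  expect_lt(null_rej / n_null, 0.10)

  for (r in seq_len(n_alt)) {
    cfg <- rows_cfg(n_infants = 30, sd_intercept = 0.5, sd_slope_limb = 0,
                    sd_resid = 0.5)
    rows <- simulate_rows(cfg, events_per_visit = 3, seed = 900 + r)
    rows <- rows[rows$window == "during", ]
    fw <- fit_model(model_spec("median_during", "timepoint_by_limb",
                               "intercept", "REML"), rows)
    fo <- fit_model(model_spec("median_during", "timepoint_by_limb",
                               "none", "REML"), rows)
    if (ranova_random(fw, fo)$p < 0.05) alt_rej <- alt_rej + 1L
  }
  expect_gte(alt_rej / n_alt, 0.9)

  # identical fits give LRT exactly 0
  cfg <- rows_cfg(n_infants = 8)
  rows <- simulate_rows(cfg, 2, 57)
  f <- fit_model(model_spec("median", "window_by_timepoint", "slope"), rows)
  expect_equal(ranova_random(f, f)$LRT, 0)
})

test_that("contrasts recover cell mean differences and Bonferroni scales p", {
  set.seed(58)
  d <- expand.grid(infant_id = sprintf("i%02d", 1:20),
                   time_point = c(4, 6, 9, 12), event_id = 1:4,
                   limb = c("arm", "leg"), window = "during",
                   stringsAsFactors = FALSE)
  d$median <- 1 + 0.5 * (d$limb == "leg") + rnorm(nrow(d), 0, 0.3)
  fit <- fit_model(model_spec("median_during", "timepoint_by_limb",
                              "intercept"), d)
  ct <- emm_contrasts(fit, "limb")
  cell_diff <- mean(d$median[d$limb == "arm"]) -
    mean(d$median[d$limb == "leg"])
  expect_equal(ct$estimate, cell_diff, tolerance = 1e-6)
  expect_equal(ct$p_bonferroni, pmin(1, nrow(ct) * ct$p))
  expect_equal(ct$cohens_f, abs(ct$t) / sqrt(fit$n_obs))

  ct4 <- emm_contrasts(fit, "limb_by_timepoint")
  expect_equal(nrow(ct4), 4)
  expect_equal(ct4$p_bonferroni, pmin(1, 4 * ct4$p))
  expect_error(emm_contrasts(fit, "window"), "not in the model")
})

test_that("Nakagawa R2 matches a known variance decomposition", {
  cfg <- rows_cfg(n_infants = 10, sd_intercept = 0, sd_slope_limb = 0)
  rows <- simulate_rows(cfg, 3, 59)
  fit <- fit_model(model_spec("median", "window_by_timepoint", "intercept"),
                   rows)
  r2 <- r2_nakagawa(fit)
  expect_lt(r2["conditional"] - r2["marginal"], 0.02)  # no real random var

  # constructed decomposition: var_fixed 1.0, var_random 0.5, resid 0.5
  set.seed(60)
  n_g <- 100; n_per <- 50
  g <- rep(sprintf("i%03d", 1:n_g), each = n_per)
  x <- rep(c(-1, 1), length.out = n_g * n_per)
  b <- rnorm(n_g, 0, sqrt(0.5))[rep(1:n_g, each = n_per)]
  d <- data.frame(infant_id = g, time_point = 4, event_id = 1,
                  limb = "arm", window = "during",
                  median = 1 * x + b + rnorm(n_g * n_per, 0, sqrt(0.5)))
  d$x <- x
  fit2 <- fit_model(model_spec("median_during", "x", "intercept"), d)
  r2b <- r2_nakagawa(fit2)
  expect_equal(unname(r2b["marginal"]), 0.50, tolerance = 0.04)
  expect_equal(unname(r2b["conditional"]), 0.75, tolerance = 0.04)
})

test_that("the full suite reports all four model families", {
  cfg <- rows_cfg(n_infants = 12, sd_resid = 0.6)
  rows <- simulate_rows(cfg, events_per_visit = 4, seed = 61)
  rep <- run_full_suite(rows)
  expect_s3_class(rep, "coupling_report")
  expect_equal(rep$model_comparison$n_candidates, 8)
  expect_equal(nrow(rep$model_comparison$table), 8)
  expect_named(rep$per_window, c("base", "pre", "during"))
  expect_named(rep$diffs, c("pre", "during"))
  for (fam in rep$per_window) {
    expect_s3_class(fam$anova, "data.frame")
    expect_s3_class(fam$contrasts, "data.frame")
  }
  expect_true(all(c("LRT", "df", "p") %in% names(rep$global$ranova)))
  # under the default generator the full model should win on logLik
  expect_true(is.character(rep$model_comparison$best))
})

test_that("ranova_random agrees with lmerTest's ranova", {
  cfg <- rows_cfg(n_infants = 15, sd_intercept = 0.4)
  rows <- simulate_rows(cfg, events_per_visit = 3, seed = 62)
  rows <- rows[rows$window == "pre", ]
  fw <- fit_model(model_spec("median_pre", "timepoint_by_limb",
                             "intercept", "REML"), rows)
  fo <- fit_model(model_spec("median_pre", "timepoint_by_limb",
                             "none", "REML"), rows)
  mine <- ranova_random(fw, fo)
  ref <- as.data.frame(lmerTest::ranova(fw$fit))
  expect_equal(mine$LRT, ref$LRT[2], tolerance = 1e-6)
  expect_equal(mine$df, ref$Df[2])
})
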