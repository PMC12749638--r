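# Linear mixed-effects analysis of window-median acceleration.
#
# Four model families, mirroring the standard analysis of event-locked
# window medians:
#   global:   median ~ Time_Window * Time_Point * Limb + (1 + Limb | infant)
#   window:   median ~ Time_Window * Time_Point     + (1 + Limb | infant)
#   per-window (base/pre/during): median_w ~ Time_Point * Limb
#                                             + (1 + Limb | infant)
#   diffs (pre-base, during-base): diff_w ~ Time_Point * Limb + (1 | infant)
# Model comparison (AIC/BIC/logLik, LRT) under ML; reported coefficients,
# Type-II Satterthwaite ANOVA and EMM contrasts under REML.

factorise_rows <- function(rows) {
  rows$Time_Point <- factor(rows$time_point, levels = tp_levels)
  if ("window" %in% names(rows))
    rows$Time_Window <- factor(rows$window,
                               levels = intersect(c("base", "pre", "during",
                                                    "diff_pre", "diff_during"),
                                                  unique(rows$window)))
  if ("limb" %in% names(rows))
    rows$Limb <- factor(rows$limb, levels = c("arm", "leg"))
  rows$infant <- factor(rows$infant_id)
  rows
}

#' Mixed-model specification
#'
#' @param response which dependent measure the model uses: `"median"`
#'   (all three windows), `"median_base"`, `"median_pre"`,
#'   `"median_during"` (one window), `"diff_pre"` or `"diff_during"`
#'   (baseline-corrected differences).
#' @param fixed fixed-effects structure: `"full"` (triple interaction),
#'   `"window_by_timepoint"`, `"timepoint_by_limb"`, or a formula RHS
#'   string.
#' @param random `"slope"` for `(1 + Limb | infant)`, `"intercept"` for
#'   `(1 | infant)`, `"none"` for a fixed-effects-only fit.
#' @param estimation `"REML"` or `"ML"`.
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(response = "median",
                       fixed = c("full", "window_by_timepoint",
                                 "timepoint_by_limb", "main_effects",
                                 "two_way"),
                       random = c("slope", "intercept", "none"),
                       estimation = c("REML", "ML")) {
  fixed <- fixed[1]
  random <- match.arg(random)
  estimation <- match.arg(estimation)
  rhs <- switch(fixed,
    full = "Time_Window * Time_Point * Limb",
    window_by_timepoint = "Time_Window * Time_Point",
    timepoint_by_limb = "Time_Point * Limb",
    main_effects = "Time_Window + Time_Point + Limb",
    two_way = "(Time_Window + Time_Point + Limb)^2",
    fixed)
  rterm <- switch(random,
    slope = "(1 + Limb | infant)",
    intercept = "(1 | infant)",
    none = NULL)
  structure(list(response = response, fixed = fixed, random = random,
                 estimation = estimation, rhs = rhs, rterm = rterm),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rhs <- paste(c(spec$rhs, spec$rterm), collapse = " + ")
  as.formula(paste("median ~", rhs))
}

# Select and shape rows for a spec's response.
spec_rows <- function(spec, rows) {
  rows <- factorise_rows(rows)
  win <- sub("^median_", "", spec$response)
  if (spec$response == "median") {
    out <- rows[rows$window %in% c("base", "pre", "during"), , drop = FALSE]
  } else if (win %in% c("base", "pre", "during")) {
    out <- rows[rows$window == win, , drop = FALSE]
  } else if (spec$response %in% c("diff_pre", "diff_during")) {
    out <- rows[rows$window == spec$response, , drop = FALSE]
    if (!nrow(out))
      stop_fmt("fit_model: no '%s' rows; run baseline_diffs() first",
               spec$response)
  } else stop_fmt("fit_model: unknown response '%s'", spec$response)
  droplevels(out)
}

#' Fit a mixed model for window medians
#'
#' @param spec a [model_spec()].
#' @param rows event-level summary rows ([window_medians()], possibly
#'   augmented with [baseline_diffs()] output).
#' @return a list of class `fit_result`: the `lmerTest` fit plus
#'   coefficients, variance components, `logLik`/`AIC`/`BIC`, parameter
#'   count and convergence/singularity flags.
#' @export
fit_model <- function(spec, rows) {
  d <- spec_rows(spec, rows)
  if (nlevels(d$infant) < 2L) stop_fmt("fit_model: need >= 2 infants")
  reml <- spec$estimation == "REML"
  if (spec$random == "none") {
    fit <- lm(spec_formula(spec), data = d)
    if (reml) {
      # Harville REML log-likelihood of a fixed-effects model, so that
      # matched-REML comparisons against mixed fits are on the same scale
      X <- model.matrix(fit)
      n <- nrow(X); p <- ncol(X)
      rss <- sum(fit$residuals^2)
      s2 <- rss / (n - p)
      val <- -0.5 * ((n - p) * (log(2 * pi) + log(s2) + 1) +
                       as.numeric(determinant(crossprod(X))$modulus))
      ll <- structure(val, df = p + 1, nobs = n, class = "logLik")
    } else {
      ll <- logLik(fit)
    }
    vc <- NULL
    singular <- FALSE
    conv <- TRUE
  } else {
    # build the call with the data embedded so that downstream refits
    # (e.g. lmerTest::ranova) can re-evaluate it in any environment
    fit <- suppressMessages(do.call(lmerTest::lmer,
                                    list(spec_formula(spec), data = d,
                                         REML = reml)))
    ll <- logLik(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    singular <- lme4::isSingular(fit)
    conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L
  }
  cf <- if (spec$random == "none") summary(fit)$coefficients
        else summary(fit)$coefficients
  k <- attr(ll, "df")
  structure(list(spec = spec, fit = fit, data = d,
                 coefficients = cf, varcor = vc,
                 logLik = as.numeric(ll), n_params = k,
                 AIC = 2 * k - 2 * as.numeric(ll),
                 BIC = k * log(nobs(fit)) - 2 * as.numeric(ll),
                 sigma = sigma(fit), n_obs = nobs(fit),
                 converged = conv, singular = singular),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s ~ %s + %s [%s]\n", x$spec$response,
              x$spec$rhs, x$spec$rterm %||% "(none)", x$spec$estimation))
  cat(sprintf("  logLik %.2f | AIC %.2f | BIC %.2f | npar %d | n %d%s%s\n",
              x$logLik, x$AIC, x$BIC, x$n_params, x$n_obs,
              if (!x$converged) " | NOT CONVERGED" else "",
              if (x$singular) " | singular" else ""))
  invisible(x)
}

#' Information-criterion arithmetic
#'
#' `aic_from(logLik, n_params)` and `lrt_stat(logLik_full, logLik_reduced)`
#' implement the identities `AIC = 2k - 2l` and `LRT = 2(l1 - l0)` used in
#' model-comparison tables.
#'
#' @param logLik,logLik_full,logLik_reduced log-likelihoods.
#' @param n_params parameter count.
#' @return a number.
#' @export
aic_from <- function(logLik, n_params) 2 * n_params - 2 * logLik

#' @rdname aic_from
#' @export
lrt_stat <- function(logLik_full, logLik_reduced)
  2 * (logLik_full - logLik_reduced)

#' Compare fitted models
#'
#' AIC/BIC/logLik table for a set of fits; for nested pairs (requested via
#' `lrt_pairs`, indices into `fits`) a likelihood-ratio chi-square test
#' with `df =` difference in parameter count.
#'
#' @param fits list of [fit_model()] results on identical data.
#' @param lrt_pairs list of `c(full, reduced)` index pairs.
#' @return list with `table` (one row per fit) and `lrt` (one row per
#'   pair).
#' @export
compare_models <- function(fits, lrt_pairs = NULL) {
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f)
      paste(f$spec$fixed, f$spec$random, sep = "/"), character(1))
  tab <- data.frame(
    model = names(fits),
    n_params = vapply(fits, function(f) f$n_params, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    BIC = vapply(fits, function(f) f$BIC, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  lrt <- NULL
  if (!is.null(lrt_pairs)) {
    lrt <- do.call(rbind, lapply(lrt_pairs, function(p) {
      full <- fits[[p[1]]]; red <- fits[[p[2]]]
      if (full$n_params <= red$n_params)
        stop_fmt("compare_models: pair (%s, %s) is not full-vs-reduced",
                 names(fits)[p[1]], names(fits)[p[2]])
      if (full$n_obs != red$n_obs)
        stop_fmt("compare_models: fits are not on identical data")
      stat <- lrt_stat(full$logLik, red$logLik)
      df <- full$n_params - red$n_params
      data.frame(full = names(fits)[p[1]], reduced = names(fits)[p[2]],
                 LRT = stat, df = df,
                 p = pchisq(stat, df, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }
  list(table = tab, lrt = lrt)
}

#' Cohen's f and partial eta-squared from an F statistic
#'
#' Omnibus conventions: `partial_eta2 = NumDF * F / (NumDF * F + DenDF)`
#' and `cohens_f = sqrt(NumDF * F / DenDF)`, related by
#' `f^2 = eta2 / (1 - eta2)`.
#'
#' @param F_val F statistic.
#' @param num_df,den_df numerator and denominator degrees of freedom.
#' @return a number.
#' @export
cohens_f_from_F <- function(F_val, num_df, den_df)
  sqrt(num_df * F_val / den_df)

#' @rdname cohens_f_from_F
#' @export
partial_eta2_from_F <- function(F_val, num_df, den_df)
  num_df * F_val / (num_df * F_val + den_df)

#' Type-II ANOVA with Satterthwaite denominator df
#'
#' F tests for each fixed term (each term tested after all others of the
#' same or lower order), Satterthwaite denominator degrees of freedom,
#' plus partial eta-squared and Cohen's f effect sizes.
#'
#' @param fit a [fit_model()] result with a random structure.
#' @return data frame with `term`, `SumSq`, `MeanSq`, `NumDF`, `DenDF`,
#'   `F`, `p`, `partial_eta2`, `cohens_f`.
#' @export
anova_typeII <- function(fit) {
  if (fit$spec$random == "none")
    stop_fmt("anova_typeII: requires a mixed fit")
  a <- anova(fit$fit, type = 2, ddf = "Satterthwaite")
  out <- data.frame(term = rownames(a), SumSq = a$`Sum Sq`,
                    MeanSq = a$`Mean Sq`, NumDF = a$NumDF, DenDF = a$DenDF,
                    F = a$`F value`, p = a$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  out$partial_eta2 <- partial_eta2_from_F(out$F, out$NumDF, out$DenDF)
  out$cohens_f <- cohens_f_from_F(out$F, out$NumDF, out$DenDF)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio test of a random-effect structure
#'
#' Compares two fits with identical fixed effects but different random
#' structures (e.g. with and without the per-infant limb slope). Both fits
#' must use the same estimation method (matched-REML comparison is valid
#' because the fixed effects agree). The null distribution of variance
#' components on the boundary makes the chi-square p conservative; this is
#' noted in the output.
#'
#' @param fit_with,fit_without [fit_model()] results.
#' @return one-row data frame with `LRT`, `df`, `p` and a `note`.
#' @export
ranova_random <- function(fit_with, fit_without) {
  if (!identical(fit_with$spec$rhs, fit_without$spec$rhs))
    stop_fmt("ranova_random: fixed effects differ")
  if (!identical(fit_with$spec$estimation, fit_without$spec$estimation))
    stop_fmt("ranova_random: estimation methods differ")
  stat <- max(0, lrt_stat(fit_with$logLik, fit_without$logLik))
  df <- fit_with$n_params - fit_without$n_params
  data.frame(LRT = stat, df = df,
             p = if (df > 0) pchisq(stat, df, lower.tail = FALSE) else NA,
             note = "boundary null: chi-square p is conservative",
             stringsAsFactors = FALSE)
}

#' Estimated-marginal-mean contrasts
#'
#' Pairwise contrasts from equally weighted estimated marginal means, with
#' Satterthwaite degrees of freedom, Bonferroni adjustment over the family
#' and a t-based Cohen's f (`|t| / sqrt(N_obs)`).
#'
#' @param fit a [fit_model()] result.
#' @param family `"window"` (base/pre/during pairs), `"limb"` (leg - arm
#'   overall), or `"limb_by_timepoint"` (leg - arm within each time
#'   point).
#' @return data frame of class `contrast_table`: `contrast`, `estimate`,
#'   `SE`, `df`, `t`, `p`, `p_bonferroni`, `cohens_f`.
#' @export
emm_contrasts <- function(fit, family = c("window", "limb",
                                          "limb_by_timepoint")) {
  family <- match.arg(family)
  spec_str <- switch(family,
    window = ~Time_Window,
    limb = ~Limb,
    limb_by_timepoint = ~Limb | Time_Point)
  trm <- switch(family, window = "Time_Window", "Limb")
  if (!trm %in% all.vars(formula(fit$fit)))
    stop_fmt("emm_contrasts: factor '%s' is not in the model", trm)
  em <- suppressMessages(
    emmeans::emmeans(fit$fit, spec_str, lmer.df = "satterthwaite",
                     lmerTest.limit = 1e7, weights = "equal"))
  prs <- emmeans::contrast(em, method = "pairwise", adjust = "none")
  s <- as.data.frame(summary(prs))
  if (is.null(s$t.ratio)) s$t.ratio <- s$z.ratio
  if ("Time_Point" %in% names(s))
    s$contrast <- paste0("mo", s$Time_Point, " ", s$contrast)
  m <- nrow(s)
  out <- data.frame(contrast = s$contrast, estimate = s$estimate,
                    SE = s$SE, df = s$df, t = s$t.ratio, p = s$p.value,
                    p_bonferroni = pmin(1, m * s$p.value),
                    cohens_f = abs(s$t.ratio) / sqrt(fit$n_obs),
                    stringsAsFactors = FALSE)
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Marginal and conditional R-squared (Nakagawa)
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed
#' plus random effects (conditional):
#' `R2m = var_f / (var_f + var_r + var_e)`,
#' `R2c = (var_f + var_r) / (var_f + var_r + var_e)`, where the random
#' variance is the mean per-observation variance `tr(Z G Z') / n`.
#'
#' @param fit a [fit_model()] result with a random structure.
#' @return named numeric vector `c(marginal =, conditional =)`.
#' @export
r2_nakagawa <- function(fit) {
  mod <- fit$fit
  if (fit$spec$random == "none") {
    r2 <- summary(mod)$r.squared
    return(c(marginal = r2, conditional = r2))
  }
  var_f <- var(as.numeric(lme4::getME(mod, "X") %*% lme4::fixef(mod)))
  Z <- lme4::getME(mod, "Z")
  Lambda <- lme4::getME(mod, "Lambda")
  G <- sigma(mod)^2 * Matrix::tcrossprod(Lambda)
  var_r <- sum(Matrix::rowSums((Z %*% G) * Z)) / nrow(Z)
  var_e <- sigma(mod)^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Run the full model suite
#'
#' Fits the four model families on event-level rows and produces a
#' machine-readable report: the eight-candidate global model comparison
#' (four fixed structures -- main effects, both two-way lattices, full
#' triple interaction -- crossed with slope/intercept random structures,
#' compared under ML), then REML fits with Type-II Satterthwaite ANOVA,
#' random-effect LRTs, EMM contrasts and Nakagawa R-squared.
#'
#' @param rows event-level rows from [window_medians()]; baseline
#'   differences are computed internally if absent.
#' @return a list of class `coupling_report` with elements
#'   `model_comparison`, `global`, `window_by_timepoint`, `per_window`,
#'   `diffs`.
#' @export
run_full_suite <- function(rows) {
  if (!any(rows$window %in% c("diff_pre", "diff_during"))) {
    rows <- rbind(rows, baseline_diffs(rows[rows$window %in%
                                              c("base", "pre", "during"), ]))
  }
  # -- candidate global structures under ML ------------------------------
  fixed_lattice <- c("main_effects", "window_by_timepoint", "two_way", "full")
  cand <- list()
  for (fx in fixed_lattice) for (rd in c("slope", "intercept")) {
    nm <- paste(fx, rd, sep = "/")
    cand[[nm]] <- fit_model(model_spec("median", fx, rd, "ML"), rows)
  }
  n_cand <- length(cand)
  best <- names(cand)[which.max(vapply(cand, function(f) f$logLik,
                                       numeric(1)))]
  comp <- compare_models(cand, lrt_pairs = list(
    c("full/slope", "two_way/slope"),
    c("full/slope", "full/intercept")))
  # -- global REML fit ---------------------------------------------------
  g <- fit_model(model_spec("median", "full", "slope", "REML"), rows)
  g_noslope <- fit_model(model_spec("median", "full", "intercept", "REML"),
                         rows)
  global <- list(fit = g, anova = anova_typeII(g),
                 ranova = ranova_random(g, g_noslope),
                 r2 = r2_nakagawa(g))
  # -- window x time point -----------------------------------------------
  w <- fit_model(model_spec("median", "window_by_timepoint", "slope"), rows)
  w_noslope <- fit_model(model_spec("median", "window_by_timepoint",
                                    "intercept"), rows)
  window_by_timepoint <- list(fit = w, anova = anova_typeII(w),
                              ranova = ranova_random(w, w_noslope),
                              contrasts = emm_contrasts(w, "window"))
  # -- per-window time point x limb --------------------------------------
  per_window <- lapply(c(base = "median_base", pre = "median_pre",
                         during = "median_during"), function(resp) {
    f <- fit_model(model_spec(resp, "timepoint_by_limb", "slope"), rows)
    list(fit = f, anova = anova_typeII(f),
         contrasts = emm_contrasts(f, "limb_by_timepoint"))
  })
  # -- baseline-corrected differences (intercept-only random) ------------
  diffs <- lapply(c(pre = "diff_pre", during = "diff_during"),
                  function(resp) {
    f <- fit_model(model_spec(resp, "timepoint_by_limb", "intercept"), rows)
    list(fit = f, anova = anova_typeII(f),
         contrasts = emm_contrasts(f, "limb_by_timepoint"))
  })
  structure(list(model_comparison = c(comp, list(best = best,
                                                 n_candidates = n_cand)),
                 global = global,
                 window_by_timepoint = window_by_timepoint,
                 per_window = per_window, diffs = diffs),
            class = "coupling_report")
}

#' @export
print.coupling_report <- function(x, ...) {
  cat("<coupling_report>\n")
  cat(sprintf("  candidate global models: %d (best by logLik: %s)\n",
              x$model_comparison$n_candidates, x$model_comparison$best))
  cat(sprintf("  global R2: marginal %.3f, conditional %.3f\n",
              x$global$r2["marginal"], x$global$r2["conditional"]))
  a <- x$window_by_timepoint$anova
  tw <- a[a$term == "Time_Window", ]
  if (nrow(tw))
    cat(sprintf("  Time_Window: F(%d, %.1f) = %.2f, p = %.3g, f = %.3f\n",
                tw$NumDF, tw$DenDF, tw$F, tw$p, tw$cohens_f))
  invisible(x)
}
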