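## Regression layer. All fits are ordinary least squares via stats::lm; results
## are wrapped into a tidy `sr_reg` object (one row per term with Wald 95% CIs)
## carrying n, r-squared, adjusted r-squared and residual SE as reported in the
## usual journal table layout.

sr_reg <- function(fit, outcome, level = 0.95) {
  sm <- summary(fit)
  co <- sm$coefficients
  a <- 1 - level
  tq <- stats::qt(1 - a / 2, df = fit$df.residual)
  terms <- data.frame(
    term = rownames(co),
    estimate = co[, 1],
    se = co[, 2],
    ci_low = co[, 1] - tq * co[, 2],
    ci_high = co[, 1] + tq * co[, 2],
    p = co[, 4],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(outcome = outcome, terms = terms, n = length(fit$residuals),
         r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         residual_se = sm$sigma, df_residual = fit$df.residual,
         level = level, vcov = stats::vcov(fit), fit = fit),
    class = "sr_reg"
  )
}

#' @export
print.sr_reg <- function(x, digits = 4, ...) {
  cat(sprintf("OLS: %s  (n = %d, R^2 = %.3f, adj. R^2 = %.3f, residual SE = %.3f)\n",
              x$outcome, x$n, x$r_squared, x$adj_r_squared, x$residual_se))
  t <- x$terms
  t[-1] <- lapply(t[-1], round, digits = digits)
  print(t, row.names = FALSE)
  invisible(x)
}

#' @export
coef.sr_reg <- function(object, ...) {
  stats::setNames(object$terms$estimate, object$terms$term)
}

reg_estimate <- function(x, term) {
  i <- match(term, x$terms$term)
  if (is.na(i)) stop("term not found: ", term, call. = FALSE)
  x$terms[i, ]
}

#' Linear time trend across waves on the complete-case sample
#'
#' Regresses the chosen outcome on wave (numeric 1..3): the estimate on `wave`
#' is the per-wave change. SR uses the pooled-longitudinal scoring so values
#' are comparable across waves.
#'
#' @param cohort A [cohort_table()]; internally restricted to participants with
#'   E and P at all three waves.
#' @param outcome `"E"`, `"P"` or `"SR"`.
#' @param basis `"dep"` or `"dis"` (which symptom scale defines P / SR).
#' @param config An [sr_config()].
#' @param categorical_wave If `TRUE`, wave enters as a factor instead of a
#'   numeric trend.
#' @return An `sr_reg`.
#' @export
fit_trend <- function(cohort, outcome = c("SR", "E", "P"), basis = c("dep", "dis"),
                      config = NULL, categorical_wave = FALSE) {
  outcome <- match.arg(outcome)
  basis <- match.arg(basis)
  config <- as_sr_config(config)
  p_var <- if (basis == "dep") "phq9" else "ghq12"
  cc <- complete_case_subset(cohort, c("E", p_var), config)
  if (length(unique(cc$observations$wave)) < 2L) {
    stop("design error: fewer than 2 distinct waves", call. = FALSE)
  }
  if (outcome == "SR") {
    f <- sr_fit(cc, basis, "pooled_complete_cases", config)
    d <- f$scores
    d$y <- if (config$standardise_sr) d$standardised else d$raw
  } else {
    d <- score_cohort(cc, config)
    d$y <- if (outcome == "E") d$E else d[[p_var]]
  }
  d <- d[!is.na(d$y), , drop = FALSE]
  d$wave_t <- if (categorical_wave) factor(d$wave) else as.numeric(d$wave)
  sr_reg(stats::lm(y ~ wave_t, data = d),
         outcome = paste0(outcome, "_", basis, " ~ wave"),
         level = 1 - config$significance_level)
}

#' Effect of baseline exposure on follow-up stressor reactivity
#'
#' Cross-sectional SR at a follow-up wave regressed on exposure at baseline,
#' optionally with a quadratic term to probe curvilinear (steeling /
#' inoculation) shapes.
#'
#' @param baseline_E Baseline exposure, one value per participant.
#' @param followup_SR Follow-up SR for the same participants (same order).
#' @param include_quadratic Add `baseline_E^2`.
#' @param config An [sr_config()].
#' @return An `sr_reg`.
#' @export
fit_cumulative_effect <- function(baseline_E, followup_SR,
                                  include_quadratic = FALSE, config = NULL) {
  config <- as_sr_config(config)
  keep <- !is.na(baseline_E) & !is.na(followup_SR)
  d <- data.frame(E1 = baseline_E[keep], sr = followup_SR[keep])
  if (nrow(d) < 10L) {
    stop("matching error: fewer than 10 participants with both measures", call. = FALSE)
  }
  fit <- if (include_quadratic) stats::lm(sr ~ E1 + I(E1^2), data = d)
         else stats::lm(sr ~ E1, data = d)
  sr_reg(fit, "SR_followup ~ E_baseline", 1 - config$significance_level)
}

prepare_gender <- function(gender) {
  g <- factor(gender, levels = c("female", "male", "unknown"))
  droplevels(g)
}

#' Association between a baseline resilience factor and SR
#'
#' Unadjusted model `SR ~ RF`; adjusted model adds age and gender (gender is a
#' categorical with an explicit "unknown" level). A single-level gender is
#' dropped with a warning.
#'
#' @param rf Baseline resilience-factor values (support, trust or REC), one per
#'   participant.
#' @param sr SR scores at the target wave, aligned with `rf`.
#' @param adjust Include covariates.
#' @param age,gender Covariates (required when `adjust = TRUE`).
#' @param config An [sr_config()].
#' @return An `sr_reg`; the resilience-factor term is named `rf`.
#' @export
fit_rf_association <- function(rf, sr, adjust = FALSE, age = NULL, gender = NULL,
                               config = NULL) {
  config <- as_sr_config(config)
  d <- data.frame(rf = rf, sr = sr)
  if (adjust) {
    d$age <- age
    d$gender <- prepare_gender(gender)
  }
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (stats::sd(d$rf) == 0) {
    stop("singular-design error: resilience factor is constant", call. = FALSE)
  }
  if (adjust) {
    if (nlevels(droplevels(d$gender)) < 2L) {
      warning("gender has a single level; covariate dropped")
      fit <- stats::lm(sr ~ rf + age, data = d)
    } else {
      d$gender <- droplevels(d$gender)
      fit <- stats::lm(sr ~ rf + age + gender, data = d)
    }
  } else {
    fit <- stats::lm(sr ~ rf, data = d)
  }
  sr_reg(fit, if (adjust) "SR ~ RF + age + gender" else "SR ~ RF",
         1 - config$significance_level)
}

#' Multivariate model: all resilience factors plus baseline exposure
#'
#' Joint OLS of SR on support, trust, REC and baseline E (listwise complete).
#'
#' @param support,trust,rec,baseline_E Baseline predictors, aligned with `sr`.
#' @param sr SR scores at the target wave.
#' @param config An [sr_config()].
#' @param condition_threshold Design-matrix condition number above which a
#'   collinearity warning is issued (the fit is still returned).
#' @return An `sr_reg`.
#' @export
fit_multivariate <- function(support, trust, rec, baseline_E, sr, config = NULL,
                             condition_threshold = 1e6) {
  config <- as_sr_config(config)
  d <- data.frame(support = support, trust = trust, rec = rec, E = baseline_E,
                  sr = sr)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  X <- cbind(1, as.matrix(d[c("support", "trust", "rec", "E")]))
  kappa_x <- kappa(X, exact = TRUE)
  if (kappa_x > condition_threshold) {
    warning(sprintf("collinearity: design condition number %.3g", kappa_x))
  }
  fit <- stats::lm(sr ~ support + trust + rec + E, data = d)
  sr_reg(fit, "SR ~ support + trust + rec + E_baseline",
         1 - config$significance_level)
}

#' Moderation of a resilience-factor effect by baseline exposure
#'
#' Fits `SR ~ RF + E + RF:E`; the interaction coefficient measures how the
#' factor's association with reactivity changes per percentage point of
#' baseline exposure.
#'
#' @inheritParams fit_rf_association
#' @param baseline_E Baseline exposure aligned with `rf`.
#' @param center_E Center exposure at its mean before forming the interaction
#'   (changes main effects, not the interaction estimate).
#' @return An `sr_reg` with terms `rf`, `E` and `rf:E`.
#' @export
fit_moderation <- function(rf, baseline_E, sr, config = NULL, center_E = FALSE) {
  config <- as_sr_config(config)
  d <- data.frame(rf = rf, E = baseline_E, sr = sr)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (stats::sd(d$rf) == 0) {
    stop("singular-design error: resilience factor is constant", call. = FALSE)
  }
  if (center_E) d$E <- d$E - mean(d$E)
  fit <- stats::lm(sr ~ rf * E, data = d)
  sr_reg(fit, "SR ~ RF * E_baseline", 1 - config$significance_level)
}

#' Simple slopes of a moderated effect at mean and +/- 1 SD of exposure
#'
#' The conditional slope of the resilience factor at moderator value m is
#' `B_rf + B_int * m`; its variance follows from the coefficient covariance
#' (delta rule): `var(B_rf) + m^2 var(B_int) + 2 m cov`.
#'
#' @param moderation An `sr_reg` from [fit_moderation()].
#' @param e_mean,e_sd Sample mean and SD of baseline exposure.
#' @return An object of class `simple_slopes`: data.frame with the moderator
#'   level (`mean - SD`, `mean`, `mean + SD`), slope, SE and CI.
#' @export
simple_slopes <- function(moderation, e_mean, e_sd) {
  stopifnot(inherits(moderation, "sr_reg"))
  terms <- moderation$terms$term
  int_term <- grep(":", terms, value = TRUE)
  if (length(int_term) != 1L || !("rf" %in% terms)) {
    stop("configuration error: moderation fit must contain rf, E and rf:E terms",
         call. = FALSE)
  }
  b <- coef(moderation)
  V <- moderation$vcov
  levels_m <- c(`mean - SD` = e_mean - e_sd, mean = e_mean, `mean + SD` = e_mean + e_sd)
  slope <- b[["rf"]] + b[[int_term]] * levels_m
  se <- sqrt(V["rf", "rf"] + levels_m^2 * V[int_term, int_term] +
             2 * levels_m * V["rf", int_term])
  tq <- stats::qt(1 - (1 - moderation$level) / 2, df = moderation$df_residual)
  out <- data.frame(
    level = names(levels_m), moderator_value = unname(levels_m),
    slope = unname(slope), se = unname(se),
    ci_low = unname(slope - tq * se), ci_high = unname(slope + tq * se),
    row.names = NULL
  )
  structure(list(slopes = out, moderator = "baseline_E",
                 e_mean = e_mean, e_sd = e_sd), class = "simple_slopes")
}

#' @export
print.simple_slopes <- function(x, digits = 4, ...) {
  cat("Simple slopes of the resilience factor at baseline-E levels:\n")
  s <- x$slopes
  s[-1] <- lapply(s[-1], round, digits = digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg summary of a set of association p-values
#'
#' Supplementary output only: the primary reporting applies no multiplicity
#' correction.
#'
#' @param results List of `sr_reg` objects.
#' @param term Which term's p-value to collect from each fit.
#' @return Data.frame with raw and BH-adjusted p-values.
#' @export
bh_summary <- function(results, term = "rf") {
  p <- vapply(results, function(r) reg_estimate(r, term)$p, numeric(1))
  data.frame(model = names(results) %||% seq_along(results),
             p = p, p_bh = stats::p.adjust(p, "BH"), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
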