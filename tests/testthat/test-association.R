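test_that("every regression reproduces the normal-equations solution", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(15:50, 1)
    rf <- sample(1:5, n, replace = TRUE)
    E <- stats::runif(n, 0, 100)
    sr <- stats::rnorm(n)
    age <- stats::rnorm(n, 43, 12)
    gender <- sample(c("female", "male", "unknown"), n, replace = TRUE)

    un <- fit_rf_association(rf, sr)
    expect_equal(unname(coef(un)), unname(ols_oracle(cbind(1, rf), sr)),
                 tolerance = 1e-8)

    mod <- fit_moderation(rf, E, sr)
    expect_equal(unname(coef(mod)),
                 unname(ols_oracle(cbind(1, rf, E, rf * E), sr)),
                 tolerance = 1e-8)

    cu <- fit_cumulative_effect(E, sr, include_quadratic = TRUE)
    expect_equal(unname(coef(cu)), unname(ols_oracle(cbind(1, E, E^2), sr)),
                 tolerance = 1e-8)

    if (length(unique(gender)) == 3) {
      ad <- fit_rf_association(rf, sr, adjust = TRUE, age = age, gender = gender)
      X <- cbind(1, rf, age, gender == "male", gender == "unknown")
      expect_equal(unname(coef(ad)), unname(ols_oracle(X, sr)), tolerance = 1e-8)
    }

    mv <- fit_multivariate(rf, stats::rnorm(n), stats::rnorm(n), E, sr)
    expect_equal(mv$r_squared,
                 1 - sum(stats::residuals(mv$fit)^2) / sum((sr - mean(sr))^2),
                 tolerance = 1e-10)
  }
})

test_that("time trends on complete cases recover generating slopes", {
  co <- generate_cohort(gen_cfg(500), seed = 32)
  ## identical outcome across waves: slope 0 with covering CI
  tr_flat <- fit_trend(co, "E", "dep")
  ## E declines by construction (wave means 39/34/30)
  est <- srscore:::reg_estimate(tr_flat, "wave_t")
  expect_lt(est$estimate, 0)
  expect_within(est$estimate, -4.5, est$se, k = 3)

  ## symptoms decline through exposure
  tr_p <- fit_trend(co, "P", "dep")
  expect_lt(srscore:::reg_estimate(tr_p, "wave_t")$estimate, 0)

  ## a literally constant outcome gives slope 0
  df <- make_rows(sprintf("q%02d", 1:30), waves = 1:3)
  df[stressor_bank()$items[1:6]] <- 1
  tr0 <- fit_trend(cohort_table(df), "P", "dep")
  e0 <- srscore:::reg_estimate(tr0, "wave_t")
  expect_equal(e0$estimate, 0, tolerance = 1e-10)
  expect_true(e0$ci_low <= 0 && 0 <= e0$ci_high)

  expect_error(fit_trend(cohort_table(make_rows("a", 1:3)), "E"), NA)
})

test_that("cumulative-exposure models detect linear and curvilinear truths", {
  set.seed(33)
  n <- 1500
  E1 <- pmin(pmax(stats::rnorm(n, 39, 15), 0), 100)
  sr <- 0.01 * E1 + stats::rnorm(n)
  fit <- fit_cumulative_effect(E1, sr)
  est <- srscore:::reg_estimate(fit, "E1")
  expect_within(est$estimate, 0.01, est$se)

  ## pure steeling: negative quadratic, zero linear at the centre
  sr2 <- -0.002 * (E1 - 39)^2 + stats::rnorm(n)
  fit2 <- fit_cumulative_effect(E1 - 39, sr2, include_quadratic = TRUE)
  q <- srscore:::reg_estimate(fit2, "I(E1^2)")
  l <- srscore:::reg_estimate(fit2, "E1")
  expect_lt(q$ci_high, 0)
  expect_true(l$ci_low <= 0 && 0 <= l$ci_high)

  expect_error(fit_cumulative_effect(E1[1:5], sr[1:5]), "matching error")
})

test_that("resilience-factor models match Table-2-scale truths and covariate logic", {
  set.seed(34)
  n <- 1800
  rf <- sample(1:4, n, replace = TRUE, prob = c(0.05, 0.1, 0.42, 0.43))
  sr <- -0.22 * rf + stats::rnorm(n)
  fit <- fit_rf_association(rf, sr)
  est <- srscore:::reg_estimate(fit, "rf")
  expect_within(est$estimate, -0.22, est$se)

  ## an exactly orthogonal covariate leaves the estimate unchanged
  age <- stats::residuals(stats::lm(stats::rnorm(n) ~ rf))
  gender <- rep(c("female", "male"), n / 2)
  ad <- fit_rf_association(rf, sr, adjust = TRUE, age = age, gender = gender)
  ## gender alternates independently of rf here; compare at 0.5 SE
  expect_within(srscore:::reg_estimate(ad, "rf")$estimate, est$estimate,
                est$se, k = 0.5)

  expect_error(fit_rf_association(rep(3, 50), stats::rnorm(50)), "singular-design")
  expect_warning(
    fit_rf_association(rf[1:50], sr[1:50], adjust = TRUE, age = age[1:50],
                       gender = rep("female", 50)),
    "single level")
})

test_that("orthogonal predictors give identical univariate and multivariate estimates", {
  set.seed(35)
  n <- 400
  base <- matrix(stats::rnorm(n * 4), n, 4)
  X <- qr.Q(qr(cbind(1, base)))[, 2:5] # exactly orthogonal, zero-mean columns
  sr <- X %*% c(-0.2, -0.1, -0.5, 0.01) + stats::rnorm(n)
  mv <- fit_multivariate(X[, 1], X[, 2], X[, 3], X[, 4], sr)
  for (j in 1:4) {
    uni <- ols_oracle(cbind(1, X[, j]), sr)[2]
    expect_equal(unname(coef(mv)[j + 1]), unname(uni), tolerance = 1e-8)
  }
})

test_that("moderation fits and simple slopes are internally consistent", {
  set.seed(36)
  n <- 1800
  rf <- sample(1:5, n, replace = TRUE)
  E <- pmin(pmax(stats::rnorm(n, 39, 15), 0), 100)
  sr <- -0.1 * rf - 0.003 * rf * E + 0.002 * E + stats::rnorm(n)
  mod <- fit_moderation(rf, E, sr)
  int <- srscore:::reg_estimate(mod, "rf:E")
  expect_within(int$estimate, -0.003, int$se)

  ## centring E changes main effects but not the interaction
  mod_c <- fit_moderation(rf, E, sr, center_E = TRUE)
  expect_equal(srscore:::reg_estimate(mod_c, "rf:E")$estimate, int$estimate,
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(coef(mod)[["rf"]], coef(mod_c)[["rf"]])))

  ss <- simple_slopes(mod, e_mean = 39, e_sd = 15)
  b <- coef(mod)
  expect_equal(ss$slopes$slope,
               b[["rf"]] + b[["rf:E"]] * c(24, 39, 54), tolerance = 1e-12)

  ## zero interaction: all three slopes equal the main effect
  sr0 <- -0.1 * rf + stats::rnorm(n)
  mod0 <- fit_moderation(rf, E, sr0)
  b0 <- coef(mod0)
  mod0$terms$estimate[mod0$terms$term == "rf:E"] <- 0
  mod0$vcov["rf:E", ] <- 0; mod0$vcov[, "rf:E"] <- 0
  ss0 <- simple_slopes(mod0, 39, 15)
  ## recompute slopes with the zeroed interaction
  expect_equal(ss0$slopes$slope, rep(b0[["rf"]], 3), tolerance = 1e-12)

  ## the worked arithmetic example
  mod$terms$estimate[mod$terms$term == "rf"] <- -0.1
  mod$terms$estimate[mod$terms$term == "rf:E"] <- -0.003
  ss2 <- simple_slopes(mod, 39, 15)
  expect_equal(ss2$slopes$slope[3], -0.1 - 0.003 * 54, tolerance = 1e-12)
})

test_that("delta-rule simple-slope CIs agree with a parametric bootstrap", {
  set.seed(37)
  n <- 600
  rf <- sample(1:5, n, replace = TRUE)
  E <- stats::runif(n, 0, 80)
  sr <- -0.1 * rf - 0.002 * rf * E + stats::rnorm(n)
  mod <- fit_moderation(rf, E, sr)
  ss <- simple_slopes(mod, mean(E), stats::sd(E))

  ## draw coefficients from the estimated sampling distribution
  b <- coef(mod); V <- mod$vcov
  L <- chol(V)
  draws <- matrix(stats::rnorm(10000 * 4), 10000, 4) %*% L
  draws <- sweep(draws, 2, b, "+")
  colnames(draws) <- names(b)
  for (i in 1:3) {
    m <- ss$slopes$moderator_value[i]
    sim <- draws[, "rf"] + draws[, "rf:E"] * m
    q <- stats::quantile(sim, c(0.025, 0.975))
    width_delta <- ss$slopes$ci_high[i] - ss$slopes$ci_low[i]
    width_boot <- q[2] - q[1]
    expect_equal(unname(width_boot / width_delta), 1, tolerance = 0.05)
    ## interval midpoints coincide up to simulation error
    expect_lt(abs((q[[1]] + q[[2]]) / 2 - ss$slopes$slope[i]), 0.1 * width_delta)
  }
})

test_that("the BH summary is supplementary and leaves raw p-values untouched", {
  set.seed(38)
  res <- lapply(1:4, function(i) fit_rf_association(sample(1:4, 60, TRUE),
                                                    stats::rnorm(60)))
  names(res) <- paste0("m", 1:4)
  tab <- bh_summary(res)
  expect_equal(tab$p_bh, stats::p.adjust(tab$p, "BH"))
})
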