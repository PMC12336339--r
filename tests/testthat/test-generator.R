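test_that("Spearman-Brown inversion is exact", {
  expect_equal(calibrate_scale_correlation(0.80, 6), 0.4)
  for (case in list(c(0.88, 9), c(0.85, 12), c(0.80, 6))) {
    r <- calibrate_scale_correlation(case[1], case[2])
    k <- case[2]
    expect_equal(k * r / (1 + (k - 1) * r), case[1], tolerance = 1e-10)
  }
  expect_error(calibrate_scale_correlation(1, 6), "domain error")
  expect_error(calibrate_scale_correlation(0.5, 1), "domain error")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_wave1 = 200)
  c1 <- generate_cohort(cfg, seed = 10)
  c2 <- generate_cohort(cfg, seed = 10)
  expect_identical(c1$observations, c2$observations)
  c3 <- generate_cohort(cfg, seed = 11)
  expect_false(identical(c1$observations, c3$observations))
  ## the caller's RNG stream is not disturbed
  set.seed(1); before <- stats::rnorm(1)
  set.seed(1); invisible(generate_cohort(cfg, seed = 10)); after <- stats::rnorm(1)
  expect_identical(before, after)
})

test_that("full retention and no missingness keep every participant complete", {
  co <- generate_cohort(gen_cfg(120), seed = 12)
  expect_equal(nrow(co$observations), 360)
  cc <- complete_case_subset(co, c("E", "phq9", "ghq12", "rec", "support", "trust"))
  expect_equal(nrow(cc$observations), 360)
})

test_that("dropout and entry reproduce the configured wave sizes", {
  cfg <- generator_config(n_wave1 = 2000, retention = c(0.5, 0.274),
                          new_entrants = c(500L, 30L))
  co <- generate_cohort(cfg, seed = 13)
  n_w <- table(co$observations$wave)
  expect_within(n_w[[2]], 2000 * 0.5 + 500, sqrt(2000 * 0.25), k = 3)
  expect_gt(n_w[[1]], n_w[[2]])
  expect_gt(n_w[[2]], n_w[[3]])
  ## new entrants exist at waves 2 and 3
  w1_ids <- co$observations$participant_id[co$observations$wave == 1]
  w2_ids <- co$observations$participant_id[co$observations$wave == 2]
  expect_gt(length(setdiff(w2_ids, w1_ids)), 0)
})

test_that("baseline moments track the calibration targets at the study size", {
  co <- generate_cohort(default_config(), seed = 314)
  sc <- score_cohort(co)
  b <- sc[sc$wave == 1, ]
  tg <- srscore_calibration()$targets
  mc_se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  expect_within(mean(b$E, na.rm = TRUE), tg$exposure$mean[1], mc_se(b$E))
  expect_within(mean(b$phq9, na.rm = TRUE), tg$phq9$mean, mc_se(b$phq9))
  expect_within(mean(b$ghq12, na.rm = TRUE), tg$ghq12$mean, mc_se(b$ghq12))
  expect_within(mean(b$rec, na.rm = TRUE), tg$rec$mean, mc_se(b$rec))
  rel <- reliability_report(co)
  a1 <- rel[rel$wave == 1, ]
  expect_lt(abs(a1$alpha[a1$scale == "phq9"] - 0.88), 0.02)
  expect_lt(abs(a1$alpha[a1$scale == "ghq12"] - 0.85), 0.02)
  expect_lt(abs(a1$alpha[a1$scale == "rec"] - 0.80), 0.02)
})

test_that("doubling the support-to-REC path doubles the recovered path", {
  co1 <- generate_cohort(gen_cfg(2000, rf = list(a = 0.25, b = 0, c_prime = 0,
                                                 trust = 0)), seed = 15)
  co2 <- generate_cohort(gen_cfg(2000, rf = list(a = 0.5, b = 0, c_prime = 0,
                                                 trust = 0)), seed = 15)
  slope <- function(co) {
    sc <- score_cohort(co)
    b <- sc[sc$wave == 1, ]
    f <- stats::lm(rec ~ support, b)
    c(stats::coef(f)[["support"]], summary(f)$coefficients["support", 2])
  }
  s1 <- slope(co1); s2 <- slope(co2)
  expect_within(s2[1], 2 * s1[1], sqrt(s2[2]^2 + 4 * s1[2]^2))
})

test_that("switching off reactivity and residual noise collapses the E-P scatter", {
  cfg <- gen_cfg(600, residual_noise_scale = 0)
  cfg$reactivity_share <- 0
  co <- generate_cohort(cfg, seed = 16)
  f <- sr_fit(co, "dep", "per_wave", sr_config(standardise_sr = FALSE))
  ## residual spread collapses to discretisation noise (documented tolerance:
  ## under 2 points on the 0-27 scale, against ~5 under the default noise)
  expect_lt(stats::sd(f$scores$raw), 2)
})

test_that("a wave-specific availability mask restricts generated items", {
  bank <- stressor_bank(availability = list(
    `1` = sprintf("s%02d", 1:17), `2` = sprintf("s%02d", 1:16),
    `3` = sprintf("s%02d", 1:17)))
  co <- generate_cohort(gen_cfg(150, bank = bank), seed = 17)
  w2 <- co$observations[co$observations$wave == 2, ]
  expect_true(all(is.na(w2$s17)))
  ex <- score_exposure(co)
  expect_equal(unique(ex$n_administered[ex$wave == 2]), 16L)
})

test_that("distress-dependent dropout selectively retains the less burdened", {
  cfg_mcar <- generator_config(n_wave1 = 1500, dropout_distress_weight = 0)
  cfg_dep <- generator_config(n_wave1 = 1500, dropout_distress_weight = 1.5)
  mean_w2_of_w1 <- function(cfg) {
    co <- generate_cohort(cfg, seed = 18)
    sc <- score_cohort(co)
    w2 <- sc$participant_id[sc$wave == 2]
    mean(sc$phq9[sc$wave == 1 & sc$participant_id %in% w2], na.rm = TRUE)
  }
  expect_lt(mean_w2_of_w1(cfg_dep), mean_w2_of_w1(cfg_mcar))
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(retention = c(1.2, 0.5)))
  expect_error(generator_config(distress_share = 1.2))
  expect_error(generator_config(exposure_autocorr = 1))
})
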