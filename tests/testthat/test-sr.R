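test_that("the normative line interpolates exact polynomial data", {
  E <- seq(0, 100, by = 5)
  P <- 2 + 0.12 * E
  l1 <- fit_normative_line(E, P, 1)
  expect_equal(l1$rss, 0, tolerance = 1e-16)
  expect_equal(unname(l1$coefficients), c(2, 0.12), tolerance = 1e-10)
  expect_equal(predict(l1, c(0, 50)), c(2, 8), tolerance = 1e-10)

  set.seed(2)
  P2 <- 2 + 0.1 * E + stats::rnorm(length(E))
  expect_lte(fit_normative_line(E, P2, 2)$rss, fit_normative_line(E, P2, 1)$rss)

  expect_error(fit_normative_line(rep(10, length(P)), P, 1), "singular-design")
  expect_error(fit_normative_line(E[1:2], P[1:2], 1), "sample-size")
})

test_that("a generated quadratic coefficient is recovered within 2 SE", {
  set.seed(8)
  n <- 2000
  E <- pmin(pmax(stats::rnorm(n, 39, 15), 0), 100)
  P <- 3 + 0.05 * E + 0.004 * E^2 + stats::rnorm(n, 0, 5)
  l2 <- fit_normative_line(E, P, 2)
  se_b2 <- summary(l2$fit)$coefficients["I(E^2)", "Std. Error"]
  expect_within(l2$coefficients[["beta2"]], 0.004, se_b2)
})

test_that("degree selection behaves as a likelihood-ratio chi-squared test", {
  ## symmetric construction with an exactly zero quadratic estimate
  E <- c(-(10:1), 1:10) + 39
  P <- 0.2 * E
  sel <- select_degree(E, P + rep(c(-1, 1), 10))
  expect_equal(sel$df, 1)
  expect_gte(sel$p, 0.05)
  expect_equal(sel$degree, 1)

  ## strong curvature is detected
  set.seed(4)
  E2 <- stats::runif(500, 0, 100)
  P2 <- 0.002 * (E2 - 50)^2 + stats::rnorm(500, 0, 1)
  expect_equal(select_degree(E2, P2)$degree, 2)
})

test_that("SR residuals are centred, orthogonal to the design, and unit-SD when standardised", {
  co <- generate_cohort(gen_cfg(800), seed = 21)
  for (mode in c("per_wave", "pooled_complete_cases")) {
    f <- sr_fit(co, "dep", mode)
    for (scope in unique(f$scores$scope)) {
      s <- f$scores[f$scores$scope == scope, ]
      expect_lt(abs(mean(s$raw)), 1e-8)
      expect_lt(abs(stats::cor(s$raw, s$E)) * stats::sd(s$raw), 1e-8)
      if (unique(s$degree) == 2) {
        expect_lt(abs(stats::cor(s$raw, s$E^2)) * stats::sd(s$raw), 1e-8)
      }
      expect_equal(stats::sd(s$standardised), 1, tolerance = 1e-8)
    }
  }
})

test_that("lower P means lower SR, point for point, against a fixed line", {
  co <- generate_cohort(gen_cfg(300), seed = 22)
  f <- sr_fit(co, "dis", "per_wave")
  line <- f$lines$wave_1
  s <- f$scores[f$scores$scope == "wave_1", ][1:5, ]
  delta <- 2.5
  expect_equal((s$P - delta) - predict(line, s$E), s$raw - delta, tolerance = 1e-12)
})

test_that("SR is invariant to affine rescaling of E", {
  set.seed(6)
  E <- stats::rnorm(300, 39, 15)
  P <- 4 + 0.13 * E + stats::rnorm(300, 0, 4)
  l <- fit_normative_line(E, P, 1)
  l_resc <- fit_normative_line((E - 39) / 15, P, 1)
  expect_equal(P - predict(l, E), P - predict(l_resc, (E - 39) / 15),
               tolerance = 1e-8)
})

test_that("pooled and per-wave modes fit on the documented samples", {
  co <- generate_cohort(generator_config(n_wave1 = 500, new_entrants = c(50L, 20L)),
                        seed = 23)
  pooled <- sr_fit(co, "dep", "pooled_complete_cases")
  expect_length(pooled$lines, 1)
  cc <- complete_case_subset(co, c("E", "phq9"))
  expect_equal(pooled$lines[[1]]$n, sum(!is.na(score_cohort(cc)$phq9) &
                                          !is.na(score_cohort(cc)$E)))
  pw <- sr_fit(co, "dep", "per_wave")
  expect_setequal(names(pw$lines), c("wave_1", "wave_2", "wave_3"))
  ## per-wave residuals centre within each wave
  m <- tapply(pw$scores$raw, pw$scores$wave, mean)
  expect_true(all(abs(m) < 1e-8))
})

test_that("sr_fit methods expose the model surface", {
  co <- generate_cohort(gen_cfg(300), seed = 24)
  f <- sr_fit(co, "dep", "per_wave")
  expect_output(print(f), "Stressor reactivity fit")
  expect_named(coef(f), c("wave_1", "wave_2", "wave_3"))
  expect_equal(length(residuals(f)), nrow(f$scores))
  expect_equal(fitted(f) + residuals(f), f$scores$P, tolerance = 1e-12)
  pr <- predict(f, data.frame(E = c(20, 40), wave = c(1, 2)))
  expect_length(pr, 2)
  expect_false(anyNA(pr))
  s <- summary(f)
  expect_true(all(abs(s$raw_mean) < 1e-8))
})
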