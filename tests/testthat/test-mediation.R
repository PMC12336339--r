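test_that("the Baron-Kenny path identity c = c' + a*b holds exactly", {
  set.seed(41)
  for (i in 1:10) {
    n <- 200
    x <- sample(1:4, n, replace = TRUE)
    m <- 0.5 * x + stats::rnorm(n)
    y <- -0.4 * m - 0.1 * x + stats::rnorm(n)
    covs <- if (i %% 2 == 0) data.frame(age = stats::rnorm(n)) else NULL
    fit <- baron_kenny(x, m, y, covariates = covs)
    expect_lt(abs(fit$c - (fit$c_prime + fit$a * fit$b)), 1e-10)
  }
})

test_that("product-of-paths point estimates recover simulated truths", {
  set.seed(42)
  n <- 2000
  x <- sample(1:4, n, replace = TRUE)
  m <- 0.5 * x + stats::rnorm(n)
  y <- -0.4 * m + stats::rnorm(n)
  fit <- baron_kenny(x, m, y)
  se_ab <- sqrt(0.5^2 * (1 / (stats::sd(m) * sqrt(n)))^2 +
                0.4^2 * (1 / (stats::sd(x) * sqrt(n)))^2)
  expect_within(fit$indirect, -0.20, 2 * se_ab, k = 2)

  ## null mediator path
  y0 <- 0.2 * x + stats::rnorm(n)
  fit0 <- baron_kenny(x, m, y0)
  expect_lt(abs(fit0$indirect), 0.05)
})

test_that("the exposure-mediator interaction pre-check flags only real interactions", {
  set.seed(43)
  n <- 500
  x <- sample(1:4, n, replace = TRUE)
  m <- 0.5 * x + stats::rnorm(n)
  ## deterministic linear outcome: interaction exactly zero
  y_lin <- 2 + 0.3 * x - 0.5 * m
  chk <- check_xm_interaction(x, m, y_lin)
  expect_lt(abs(chk$estimate), 1e-10)

  y_int <- 0.3 * x - 0.5 * m + 0.4 * x * m + stats::rnorm(n)
  expect_warning(check_xm_interaction(x, m, y_int), "interaction")

  expect_error(check_xm_interaction(rep(2, 50), stats::rnorm(50), stats::rnorm(50)),
               "singular-design")
})

test_that("the bootstrap is reproducible under the configured seed", {
  set.seed(44)
  n <- 150
  x <- sample(1:4, n, replace = TRUE)
  m <- 0.5 * x + stats::rnorm(n)
  y <- -0.4 * m + stats::rnorm(n)
  cfg <- sr_config(n_bootstrap = 300, rng_seed = 77L)
  r1 <- bootstrap_indirect(x, m, y, config = cfg)
  r2 <- bootstrap_indirect(x, m, y, config = cfg)
  expect_identical(mediation_json(r1), mediation_json(r2))

  r3 <- bootstrap_indirect(x, m, y, config = sr_config(n_bootstrap = 300,
                                                       rng_seed = 78L))
  expect_false(identical(r1$ci_low, r3$ci_low))

  expect_true(r1$ci_low <= r1$indirect_boot_mean)
  expect_true(r1$indirect_boot_mean <= r1$ci_high)
  expect_equal(r1$n_boot, 300L)
  expect_equal(r1$interaction_check$n, n)
})

test_that("percentile and BCa intervals both cover a strong true indirect effect", {
  set.seed(45)
  n <- 400
  x <- sample(1:4, n, replace = TRUE)
  m <- 0.5 * x + stats::rnorm(n)
  y <- -0.4 * m + stats::rnorm(n)
  cfg <- sr_config(n_bootstrap = 400, rng_seed = 5L)
  pct <- bootstrap_indirect(x, m, y, config = cfg)
  bca <- bootstrap_indirect(x, m, y, config = cfg, ci_type = "bca")
  for (r in list(pct, bca)) {
    expect_lt(r$ci_low, -0.20 + 0.1)
    expect_gt(r$ci_high, -0.20 - 0.1)
    expect_lt(r$ci_high, 0)
  }
})

test_that("mediation on a generated cohort matches its configured paths", {
  co <- generate_cohort(gen_cfg(2000, rf = list(a = 0.5, b = -0.4,
                                                c_prime = -0.22, trust = 0)),
                        seed = 46)
  d <- baseline_with_sr(co, "dep")
  fit <- baron_kenny(d$support, d$rec, d$standardised)
  se_a <- summary(stats::lm(rec ~ support, d))$coefficients["support", 2]
  se_b <- summary(stats::lm(standardised ~ support + rec, d))$coefficients["rec", 2]
  expect_within(fit$a, 0.5, se_a)
  expect_within(fit$b, -0.4, se_b)
  expect_lt(abs(fit$c - (fit$c_prime + fit$a * fit$b)), 1e-10)
})
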