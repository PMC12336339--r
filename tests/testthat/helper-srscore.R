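## Builders for tiny deterministic cohorts and shared test utilities.

registry_cols <- function(bank = stressor_bank()) srscore:::cohort_columns(bank)

## A fully-answered long-format frame: every stressor 0, PHQ items 1, GHQ
## items 1, REC items 3, support 3, trust 2. Tests tweak cells from there.
make_rows <- function(ids, waves = 1:3, bank = stressor_bank()) {
  g <- expand.grid(participant_id = ids, wave = waves,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$participant_id, g$wave), ]
  n <- nrow(g)
  df <- data.frame(participant_id = g$participant_id, wave = g$wave,
                   age = 40, gender = "female", stringsAsFactors = FALSE)
  for (cl in bank$items) df[[cl]] <- 0
  for (cl in srscore:::phq_cols) df[[cl]] <- 1
  for (cl in srscore:::ghq_cols) df[[cl]] <- 1
  for (cl in srscore:::rec_cols) df[[cl]] <- 3
  df$support <- 3
  df$trust <- 2
  rownames(df) <- NULL
  df
}

## generator config without missingness/dropout, for clean reads
gen_cfg <- function(n, rf = list(a = 0, b = 0, c_prime = 0, trust = 0),
                    mo = list(support = 0, trust = 0, rec_dep = 0, rec_dis = 0),
                    cum = 0, retention = c(1, 1), entrants = c(0L, 0L), ...) {
  generator_config(
    n_wave1 = n, retention = retention, new_entrants = entrants,
    rf_paths = rf, moderation = mo, cumulative_effect = cum,
    missingness = list(stressors = c(0, 0, 0), phq9 = c(0, 0, 0),
                       ghq12 = c(0, 0, 0), rec = c(0, 0, 0),
                       support = c(0, 0, 0), trust = c(0, 0, 0),
                       age = c(0, 0, 0)),
    item_missing = 0, ...)
}

## independent normal-equations OLS oracle
ols_oracle <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

## wave-1 scores merged with wave-w SR (standardised) for a generated cohort
baseline_with_sr <- function(cohort, basis, wave = 1) {
  sc <- score_cohort(cohort)
  b1 <- sc[sc$wave == 1, ]
  f <- sr_fit(cohort, basis, "per_wave")
  s <- f$scores[f$scores$wave == wave, c("participant_id", "raw", "standardised")]
  merge(b1, s, by = "participant_id")
}

expect_within <- function(est, truth, se, k = 2) {
  expect_lt(abs(est - truth), k * se)
}
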