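## Scale scoring. Default missing-item policy is listwise per scale: a total is
## missing if any constituent item is missing (no pro-rating; pro-rating is
## available behind `prorate`).

score_sum_scale <- function(items, k, lo, hi, what, prorate = FALSE) {
  items <- as.numeric(items)
  if (length(items) != k) {
    stop(sprintf("configuration error: %s expects %d items, got %d",
                 what, k, length(items)), call. = FALSE)
  }
  bad <- !is.na(items) & (items < lo | items > hi | items != round(items))
  if (any(bad)) {
    stop(sprintf("validation error: %s item value out of range %d..%d",
                 what, lo, hi), call. = FALSE)
  }
  n_ans <- sum(!is.na(items))
  if (n_ans == 0L) return(list(value = NA_real_, n_items_answered = 0L))
  if (anyNA(items) && !prorate) return(list(value = NA_real_, n_items_answered = n_ans))
  value <- if (prorate) mean(items, na.rm = TRUE) * k else sum(items)
  list(value = value, n_items_answered = n_ans)
}

#' Score the PHQ-9 depressive-symptom scale
#'
#' Sum of nine items rated 0..3; totals range 0-27, higher = more depressive
#' symptoms. Missing if any item is missing (unless `prorate`).
#'
#' @param items Nine values in 0..3 (or `NA`).
#' @param prorate If `TRUE`, scale the mean of answered items up to 9 items.
#' @return The total score (numeric scalar, possibly `NA`).
#' @export
#' @examples
#' score_phq9(c(1, 1, 1, 1, 1, 1, 1, 1, 2))
score_phq9 <- function(items, prorate = FALSE) {
  score_sum_scale(items, 9L, 0L, 3L, "phq9", prorate)$value
}

#' Score the GHQ-12 general-distress scale
#'
#' 0-3 Likert scoring of twelve items; totals range 0-36, higher = greater
#' psychological distress.
#'
#' @inheritParams score_phq9
#' @param items Twelve values in 0..3 (or `NA`).
#' @return The total score.
#' @export
score_ghq12 <- function(items, prorate = FALSE) {
  score_sum_scale(items, 12L, 0L, 3L, "ghq12", prorate)$value
}

#' Score perceived ability to recover from stress (REC)
#'
#' Six items on a 1-5 agreement scale, half reverse-keyed. Reverse-keyed items
#' are recoded as `6 - raw`; the score is the mean of recoded items (range
#' 1-5). Missing if any item is missing.
#'
#' @param items Six values in 1..5 (or `NA`).
#' @param reverse_flags Logical vector of length 6 marking reverse-keyed items.
#'   Default: items 2, 4 and 6.
#' @return The mean score (numeric scalar, possibly `NA`).
#' @export
score_rec <- function(items, reverse_flags = rec_reverse_flags) {
  items <- as.numeric(items)
  if (length(items) != 6L) {
    stop("configuration error: rec expects 6 items, got ", length(items), call. = FALSE)
  }
  if (length(reverse_flags) != 6L || !is.logical(reverse_flags)) {
    stop("configuration error: reverse_flags must be logical of length 6", call. = FALSE)
  }
  bad <- !is.na(items) & (items < 1 | items > 5 | items != round(items))
  if (any(bad)) stop("validation error: rec item value out of range 1..5", call. = FALSE)
  recoded <- ifelse(reverse_flags, 6 - items, items)
  if (anyNA(recoded)) return(NA_real_)
  mean(recoded)
}

#' Classify probable major depressive disorder from a PHQ-9 total
#'
#' Uses the literature cutoff: total score of 10 points or higher.
#'
#' @param total PHQ-9 total score(s), 0..27 or `NA`.
#' @return Logical vector; `NA` propagates.
#' @export
classify_probable_mdd <- function(total) {
  total >= 10
}

#' Cronbach's alpha with a Feldt confidence interval
#'
#' Internal-consistency reliability: alpha = k/(k-1) (1 - sum of item
#' variances / variance of the total). Rows with any missing item are dropped
#' (listwise). The confidence interval is the Feldt F-based interval:
#' 1 - (1 - alpha) F quantiles on (n - 1, (n - 1)(k - 1)) degrees of freedom.
#'
#' @param item_matrix Numeric matrix or data.frame, respondents x items.
#' @param level Confidence level, default 0.95.
#' @return A list of class `reliability_estimate`: `alpha`, `ci_low`,
#'   `ci_high`, `k`, `n`, `level`.
#' @export
cronbach_alpha <- function(item_matrix, level = 0.95) {
  m <- as.matrix(item_matrix)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  n <- nrow(m)
  if (k < 2L) stop("configuration error: need at least 2 items", call. = FALSE)
  if (n < 3L) stop("sample-size error: need at least 3 complete respondents", call. = FALSE)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) {
    stop("undefined reliability: total score has zero variance", call. = FALSE)
  }
  item_var <- sum(apply(m, 2, stats::var))
  alpha <- k / (k - 1) * (1 - item_var / total_var)
  a <- 1 - level
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  ci_low <- 1 - (1 - alpha) * stats::qf(1 - a / 2, df1, df2)
  ci_high <- 1 - (1 - alpha) * stats::qf(a / 2, df1, df2)
  structure(list(alpha = alpha, ci_low = ci_low, ci_high = ci_high,
                 k = k, n = n, level = level),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d%% CI %.3f, %.3f), k = %d items, n = %d\n",
              x$alpha, round(100 * x$level), x$ci_low, x$ci_high, x$k, x$n))
  invisible(x)
}

#' Derived scores for every observation of a cohort
#'
#' Applies exposure and scale scoring row-wise: proportional exposure E, PHQ-9
#' and GHQ-12 totals, REC mean, the single-item factors, the probable-MDD
#' classification, and covariates.
#'
#' @param cohort A [cohort_table()].
#' @param config An [sr_config()].
#' @return A data.frame with one row per observation.
#' @export
score_cohort <- function(cohort, config = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  config <- as_sr_config(config)
  df <- cohort$observations
  ex <- score_exposure_rows(df, cohort$bank, config)

  phq_m <- as.matrix(df[phq_cols])
  ghq_m <- as.matrix(df[ghq_cols])
  rec_m <- as.matrix(df[rec_cols])
  phq <- ifelse(rowSums(is.na(phq_m)) > 0L, NA_real_, rowSums(phq_m))
  ghq <- ifelse(rowSums(is.na(ghq_m)) > 0L, NA_real_, rowSums(ghq_m))
  rec_rec <- sweep_reverse(rec_m, rec_reverse_flags)
  rec <- ifelse(rowSums(is.na(rec_rec)) > 0L, NA_real_, rowMeans(rec_rec))

  data.frame(
    participant_id = df$participant_id,
    wave = df$wave,
    age = df$age,
    gender = df$gender,
    E = ex$E,
    phq9 = phq,
    ghq12 = ghq,
    rec = rec,
    support = df$support,
    trust = df$trust,
    probable_mdd = classify_probable_mdd(phq),
    stringsAsFactors = FALSE
  )
}

## Reverse-key flagged columns of an item matrix on a 1..5 scale.
sweep_reverse <- function(m, flags) {
  m[, flags] <- 6 - m[, flags]
  m
}

#' Reliability report per scale and wave
#'
#' @param cohort A [cohort_table()].
#' @param scales Which item blocks to assess.
#' @param level Confidence level.
#' @return A data.frame: scale, wave, alpha, ci_low, ci_high, k, n.
#' @export
reliability_report <- function(cohort, scales = c("phq9", "ghq12", "rec"),
                               level = 0.95) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cohort$observations
  out <- list()
  for (sc in scales) {
    cols <- switch(sc, phq9 = phq_cols, ghq12 = ghq_cols, rec = rec_cols,
                   stop("configuration error: unknown scale ", sc, call. = FALSE))
    for (w in sort(unique(df$wave))) {
      m <- as.matrix(df[df$wave == w, cols, drop = FALSE])
      if (sc == "rec") m <- sweep_reverse(m, rec_reverse_flags)
      if (sum(stats::complete.cases(m)) < 3L) next
      r <- cronbach_alpha(m, level)
      out[[length(out) + 1L]] <- data.frame(
        scale = sc, wave = w, alpha = r$alpha, ci_low = r$ci_low,
        ci_high = r$ci_high, k = r$k, n = r$n)
    }
  }
  do.call(rbind, out)
}
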