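#' Dichotomise stressor items for one observation
#'
#' Maps each administered stressor item to 1 (occurred), 0 (did not occur) or
#' `NA` (unanswered). Length equals the number of items administered at the
#' observation's wave.
#'
#' @param obs A single-row data.frame in the cohort column registry (or a named
#'   list) carrying `wave` and the stressor columns.
#' @param bank A [stressor_bank()].
#' @return Named numeric vector over the administered items with values in
#'   \{0, 1, NA\}.
#' @export
dichotomise_stressors <- function(obs, bank = stressor_bank()) {
  wave <- as.integer(obs$wave)
  adm <- administered_items(bank, wave)
  not_adm <- setdiff(bank$items, adm)
  for (cl in not_adm) {
    if (!is.null(obs[[cl]]) && !is.na(obs[[cl]])) {
      stop(sprintf("integrity error: response for non-administered item %s at wave %d",
                   cl, wave), call. = FALSE)
    }
  }
  v <- vapply(adm, function(cl) as.numeric(obs[[cl]]), numeric(1))
  if (!all(is.na(v) | v %in% c(0, 1))) {
    stop("validation error: stressor responses must be 0, 1 or missing", call. = FALSE)
  }
  v
}

#' Proportional stressor-exposure score E
#'
#' E is the percentage of stressors endorsed: 100 x (number endorsed) /
#' denominator. By default the denominator is the number of items the
#' individual answered among those administered at the wave; with
#' `config$impute_unanswered = TRUE` unanswered items count as "did not occur"
#' and the denominator is the full administered battery. The score is missing
#' when the answered fraction falls below `config$min_item_coverage`.
#'
#' @param dichotomous Vector from [dichotomise_stressors()].
#' @param config An [sr_config()].
#' @return A list with `value` (percent in 0..100, or `NA`), `n_endorsed`,
#'   `n_answered`, `n_administered`.
#' @export
compute_exposure <- function(dichotomous, config = NULL) {
  config <- as_sr_config(config)
  if (length(dichotomous) == 0L) {
    stop("integrity error: empty stressor vector", call. = FALSE)
  }
  n_adm <- length(dichotomous)
  n_ans <- sum(!is.na(dichotomous))
  n_end <- sum(dichotomous == 1, na.rm = TRUE)
  if (n_ans / n_adm < config$min_item_coverage) {
    value <- NA_real_
  } else if (config$impute_unanswered) {
    value <- 100 * n_end / n_adm
  } else {
    value <- 100 * n_end / n_ans
  }
  list(value = value, n_endorsed = n_end, n_answered = n_ans,
       n_administered = n_adm)
}

## Vectorised row-wise exposure scoring over a long-format observation frame.
score_exposure_rows <- function(df, bank, config) {
  config <- as_sr_config(config)
  n <- nrow(df)
  E <- rep(NA_real_, n)
  n_end <- n_ans <- n_adm <- integer(n)
  for (w in 1:3) {
    idx <- which(df$wave == w)
    if (!length(idx)) next
    adm <- administered_items(bank, w)
    m <- as.matrix(df[idx, adm, drop = FALSE])
    ans <- rowSums(!is.na(m))
    end <- rowSums(m == 1, na.rm = TRUE)
    k <- length(adm)
    denom <- if (config$impute_unanswered) k else ans
    val <- 100 * end / denom
    val[ans / k < config$min_item_coverage] <- NA_real_
    val[ans == 0L] <- NA_real_
    E[idx] <- val
    n_end[idx] <- end
    n_ans[idx] <- ans
    n_adm[idx] <- k
  }
  data.frame(participant_id = df$participant_id, wave = df$wave, E = E,
             n_endorsed = n_end, n_answered = n_ans, n_administered = n_adm,
             stringsAsFactors = FALSE)
}

#' Exposure scores for every observation of a cohort
#'
#' @param cohort A [cohort_table()].
#' @param config An [sr_config()].
#' @return A data.frame with one row per observation: `participant_id`,
#'   `wave`, `E` (percent, `NA` below the coverage gate), `n_endorsed`,
#'   `n_answered`, `n_administered`.
#' @export
score_exposure <- function(cohort, config = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  score_exposure_rows(cohort$observations, cohort$bank, config)
}
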