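## Long format is canonical: one row per participant x wave. Missing = NA
## internally, empty string in CSV. Gender "unknown" is a level, not missing.

phq_cols <- sprintf("phq%02d", 1:9)
ghq_cols <- sprintf("ghq%02d", 1:12)
rec_cols <- sprintf("rec%d", 1:6)

## Brief-resilience-style keying: items 2, 4, 6 are reverse-scored.
rec_reverse_flags <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)

cohort_columns <- function(bank) {
  c("participant_id", "wave", "age", "gender", bank$items,
    phq_cols, ghq_cols, rec_cols, "support", "trust")
}

range_check <- function(df, cols, lo, hi, what) {
  for (cl in cols) {
    v <- df[[cl]]
    bad <- which(!is.na(v) & (v < lo | v > hi | v != round(v)))
    if (length(bad)) {
      stop(sprintf("validation error: %s value out of range %d..%d at row %d, column %s",
                   what, lo, hi, bad[1], cl), call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Assemble and validate a multi-wave cohort table
#'
#' @param observations A long-format data.frame, one row per participant and
#'   wave, using the documented column registry (`participant_id`, `wave`,
#'   `age`, `gender`, `s01`..`s17`, `phq01`..`phq09`, `ghq01`..`ghq12`,
#'   `rec1`..`rec6`, `support`, `trust`).
#' @param bank A [stressor_bank()] describing item availability per wave.
#'
#' @return An object of class `cohort_table` with elements `observations` and
#'   `bank`. Every row is validated: item values must lie in their documented
#'   ranges, `(participant_id, wave)` pairs must be unique, and stressor
#'   responses may only be present for items administered at that wave.
#' @export
cohort_table <- function(observations, bank = stressor_bank()) {
  stopifnot(inherits(bank, "stressor_bank"))
  df <- as.data.frame(observations, stringsAsFactors = FALSE)
  cols <- cohort_columns(bank)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("format error: missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[cols]
  if (nrow(df) < 1L) stop("integrity error: cohort must contain at least one observation",
                          call. = FALSE)

  df$participant_id <- as.character(df$participant_id)
  df$wave <- as.integer(df$wave)
  if (any(is.na(df$wave)) || !all(df$wave %in% 1:3)) {
    stop("validation error: wave must be 1, 2 or 3", call. = FALSE)
  }
  key <- paste(df$participant_id, df$wave, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("integrity error: duplicate (participant_id, wave) pair ('%s', %d)",
                 d$participant_id, d$wave), call. = FALSE)
  }

  df$gender <- as.character(df$gender)
  df$gender[is.na(df$gender) | df$gender == ""] <- "unknown"
  if (!all(df$gender %in% c("female", "male", "unknown"))) {
    stop("validation error: gender must be one of female, male, unknown", call. = FALSE)
  }
  df$age <- as.numeric(df$age)
  num_cols <- c(bank$items, phq_cols, ghq_cols, rec_cols, "support", "trust")
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])

  range_check(df, bank$items, 0L, 1L, "stressor")
  range_check(df, phq_cols, 0L, 3L, "phq9")
  range_check(df, ghq_cols, 0L, 3L, "ghq12")
  range_check(df, rec_cols, 1L, 5L, "rec")
  range_check(df, "support", 1L, 4L, "support")
  range_check(df, "trust", 0L, 4L, "trust")

  for (w in 1:3) {
    adm <- administered_items(bank, w)
    not_adm <- setdiff(bank$items, adm)
    if (length(not_adm)) {
      rows <- which(df$wave == w)
      for (cl in not_adm) {
        bad <- rows[!is.na(df[[cl]][rows])]
        if (length(bad)) {
          stop(sprintf(
            "integrity error: response for item %s not administered at wave %d (row %d)",
            cl, w, bad[1]), call. = FALSE)
        }
      }
    }
  }

  rownames(df) <- NULL
  structure(list(observations = df, bank = bank), class = "cohort_table")
}

#' Read a cohort CSV file
#'
#' CSV dialect: UTF-8, header row, the documented column registry, empty string
#' as the missing token.
#'
#' @param path File to read.
#' @param bank A [stressor_bank()].
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path, bank = stressor_bank()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = c(participant_id = "character"))
  cohort_table(df, bank)
}

#' Write a cohort to CSV
#'
#' Deterministic column order (the registry) and missing-value encoding (empty
#' string); `read_cohort(write_cohort(x))` round-trips exactly.
#'
#' @param cohort A [cohort_table()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cohort$observations[cohort_columns(cohort$bank)]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write to ", path, call. = FALSE)
  invisible(path)
}

## Registry of variable names usable in complete-case logic. "E" means an
## exposure score is computable for the row under `config`.
cc_registry <- c("E", "phq9", "ghq12", "rec", "support", "trust", "age", "gender")

variable_present <- function(df, var, bank, config) {
  switch(var,
    E = !is.na(score_exposure_rows(df, bank, config)$E),
    phq9 = rowSums(is.na(df[phq_cols])) == 0L,
    ghq12 = rowSums(is.na(df[ghq_cols])) == 0L,
    rec = rowSums(is.na(df[rec_cols])) == 0L,
    support = !is.na(df$support),
    trust = !is.na(df$trust),
    age = !is.na(df$age),
    gender = rep(TRUE, nrow(df))
  )
}

#' Complete-case subset of a cohort
#'
#' Retains exactly the participants who appear at all three waves and for whom
#' every `required` variable is non-missing at every wave; all three of each
#' retained participant's rows are kept.
#'
#' @param cohort A [cohort_table()].
#' @param required Character vector of variable names from the registry
#'   (`"E"`, `"phq9"`, `"ghq12"`, `"rec"`, `"support"`, `"trust"`, `"age"`,
#'   `"gender"`). An empty vector requires only presence at all three waves.
#' @param config An [sr_config()]; used when `"E"` is required (coverage gate).
#' @return A [cohort_table()] restricted to the complete cases.
#' @export
complete_case_subset <- function(cohort, required = character(), config = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  config <- as_sr_config(config)
  unknown <- setdiff(required, cc_registry)
  if (length(unknown)) {
    stop("configuration error: unknown variable name(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  df <- cohort$observations
  ok_row <- rep(TRUE, nrow(df))
  for (var in required) {
    ok_row <- ok_row & variable_present(df, var, cohort$bank, config)
  }
  waves_ok <- tapply(df$wave[ok_row], df$participant_id[ok_row],
                     function(w) length(unique(w)) == 3L)
  keep_ids <- names(waves_ok)[which(waves_ok)]
  keep <- df$participant_id %in% keep_ids
  if (!any(keep)) {
    stop("integrity error: complete-case subset is empty", call. = FALSE)
  }
  cohort_table(df[keep, , drop = FALSE], cohort$bank)
}

#' @export
print.cohort_table <- function(x, ...) {
  df <- x$observations
  cat(sprintf("Multi-wave cohort: %d observations, %d participants\n",
              nrow(df), length(unique(df$participant_id))))
  for (w in sort(unique(df$wave))) {
    cat(sprintf("  wave %d: n = %d\n", w, sum(df$wave == w)))
  }
  invisible(x)
}

#' @export
summary.cohort_table <- function(object, config = NULL, ...) {
  config <- as_sr_config(config)
  sc <- score_cohort(object, config)
  by_wave <- split(sc, sc$wave)
  out <- do.call(rbind, lapply(by_wave, function(d) {
    data.frame(
      wave = d$wave[1], n = nrow(d),
      E_mean = mean(d$E, na.rm = TRUE), E_sd = stats::sd(d$E, na.rm = TRUE),
      phq9_mean = mean(d$phq9, na.rm = TRUE),
      ghq12_mean = mean(d$ghq12, na.rm = TRUE),
      support_mean = mean(d$support, na.rm = TRUE),
      trust_mean = mean(d$trust, na.rm = TRUE),
      rec_mean = mean(d$rec, na.rm = TRUE)
    )
  }))
  rownames(out) <- NULL
  out
}
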