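test_that("cohort CSV round-trips exactly, including missing values", {
  df <- make_rows(sprintf("p%02d", 1:5), waves = 1)
  df$trust[c(2, 4)] <- NA
  df$age[1] <- NA
  df$phq03[3] <- NA
  co <- cohort_table(df)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_identical(co2$observations, co$observations)
  ## missing token is the empty string
  raw <- readLines(path)
  expect_true(any(grepl(",,", raw)))
})

test_that("row validation names the offence", {
  df <- make_rows("p1", waves = 1)
  df$phq04 <- 4
  expect_error(cohort_table(df), "phq9.*0\\.\\.3.*phq04")

  df <- make_rows("p1", waves = 1)
  df$rec2 <- 0
  expect_error(cohort_table(df), "rec")

  df <- make_rows("p1", waves = 1:2)
  df$wave <- c(1, 1)
  expect_error(cohort_table(df), "duplicate")

  df <- make_rows("p1", waves = 1)
  df$support <- NULL
  expect_error(cohort_table(df), "missing mandatory columns: support")

  expect_error(cohort_table(make_rows("p1", 1)[0, ]), "at least one observation")
})

test_that("responses to items not administered at a wave are rejected", {
  bank <- stressor_bank(availability = list(
    `1` = sprintf("s%02d", 1:17), `2` = sprintf("s%02d", 1:16),
    `3` = sprintf("s%02d", 1:17)))
  df <- make_rows("p1", waves = 1:3, bank = bank)
  expect_error(cohort_table(df, bank), "s17 not administered at wave 2")
  df$s17[df$wave == 2] <- NA
  expect_s3_class(cohort_table(df, bank), "cohort_table")
})

test_that("complete-case subsetting keys on presence at all 3 waves plus non-missingness", {
  df <- make_rows(c("a", "b", "c"), waves = 1:3)
  df$phq05[df$participant_id == "b" & df$wave == 2] <- NA
  co <- cohort_table(df)

  cc <- complete_case_subset(co, "phq9")
  expect_setequal(unique(cc$observations$participant_id), c("a", "c"))
  expect_equal(nrow(cc$observations), 6)

  ## b's GHQ items are complete, so the GHQ subset keeps all three
  cc_g <- complete_case_subset(co, "ghq12")
  expect_setequal(unique(cc_g$observations$participant_id), c("a", "b", "c"))

  ## empty requirement still requires presence at all three waves
  df2 <- rbind(df, make_rows("d", waves = 1:2))
  co2 <- cohort_table(df2)
  cc0 <- complete_case_subset(co2, character())
  expect_setequal(unique(cc0$observations$participant_id), c("a", "b", "c"))

  expect_error(complete_case_subset(co, "nope"), "unknown variable")
})

test_that("complete-case subsetting is idempotent and monotone", {
  co <- generate_cohort(generator_config(n_wave1 = 300, new_entrants = c(30L, 10L)),
                        seed = 3)
  cc1 <- complete_case_subset(co, c("E", "phq9"))
  cc2 <- complete_case_subset(cc1, c("E", "phq9"))
  expect_identical(cc1$observations, cc2$observations)

  ids <- function(x) unique(x$observations$participant_id)
  cc_more <- complete_case_subset(co, c("E", "phq9", "ghq12", "rec"))
  expect_true(all(ids(cc_more) %in% ids(cc1)))
})

test_that("independent block missingness yields different PHQ- and GHQ-based subsets", {
  co <- generate_cohort(generator_config(n_wave1 = 600), seed = 9)
  ids <- function(req) unique(complete_case_subset(co, req)$observations$participant_id)
  phq_ids <- ids(c("E", "phq9"))
  ghq_ids <- ids(c("E", "ghq12"))
  expect_gt(length(phq_ids), 10)
  expect_gt(length(ghq_ids), 10)
  expect_false(setequal(phq_ids, ghq_ids))
})

test_that("an empty complete-case subset is an integrity error", {
  co <- cohort_table(make_rows(c("a", "b"), waves = 1:2))
  expect_error(complete_case_subset(co, "phq9"), "integrity error")
})
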