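#' Run the full analysis pipeline
#'
#' Sequences the whole chain on a cohort (supplied or generated): scale and
#' exposure scoring, reliability, complete-case subsetting, pooled SR and time
#' trends, per-wave SR, cumulative baseline-exposure models, the
#' resilience-factor association grid (3 factors x 3 waves x
#' unadjusted/adjusted x 2 bases), the multivariate model, moderation with
#' simple slopes, and Baron-Kenny mediation with its interaction pre-check.
#' Every stage is logged with the row count it ran on.
#'
#' @param cohort A [cohort_table()], or `NULL` to generate one.
#' @param gen_config A [generator_config()] used when `cohort` is `NULL`.
#' @param config An [sr_config()]; `rng_seed` drives generation and the
#'   mediation bootstrap.
#' @param bases Which SR bases to analyse.
#' @return An object of class `sr_report`: a list of result tables and fitted
#'   objects plus a `log` data.frame and run metadata.
#' @export
run_pipeline <- function(cohort = NULL, gen_config = NULL, config = NULL,
                         bases = c("dep", "dis")) {
  config <- as_sr_config(config)
  log <- list()
  note <- function(stage, n, detail = "") {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n = n, detail = detail)
  }

  if (is.null(cohort)) {
    if (is.null(gen_config)) gen_config <- default_config()
    cohort <- generate_cohort(gen_config, config$rng_seed)
    note("generate", nrow(cohort$observations))
  }
  note("ingest", nrow(cohort$observations))

  scored <- score_cohort(cohort, config)
  note("score", sum(!is.na(scored$E)))
  reliability <- reliability_report(cohort)
  note("reliability", sum(reliability$n))

  descriptives <- summary(cohort, config)

  out <- list(cohort_n = nrow(cohort$observations), scored = scored,
              reliability = reliability, descriptives = descriptives,
              sr = list(), trends = list(), cumulative = list(),
              rf_grid = NULL, multivariate = list(), moderation = list(),
              simple_slopes = list(), mediation = list(), sensitivity = list())

  base1 <- scored[scored$wave == 1, , drop = FALSE]
  e_mean <- mean(base1$E, na.rm = TRUE)
  e_sd <- stats::sd(base1$E, na.rm = TRUE)

  rf_rows <- list()
  for (basis in bases) {
    p_var <- if (basis == "dep") "phq9" else "ghq12"

    pooled <- sr_fit(cohort, basis, "pooled_complete_cases", config)
    per_wave <- sr_fit(cohort, basis, "per_wave", config)
    out$sr[[basis]] <- list(pooled = pooled, per_wave = per_wave)
    note(paste0("sr_", basis), nrow(per_wave$scores))

    for (oc in c("E", "P", "SR")) {
      out$trends[[basis]][[oc]] <- fit_trend(cohort, oc, basis, config)
    }
    note(paste0("trend_", basis), out$trends[[basis]]$SR$n)

    sw <- per_wave$scores
    sw$sr <- if (config$standardise_sr) sw$standardised else sw$raw
    srw <- function(w) sw[sw$wave == w, c("participant_id", "sr")]
    for (w in 2:3) {
      d <- merge(base1[c("participant_id", "E")], srw(w), by = "participant_id")
      if (nrow(d) >= 10) {
        out$cumulative[[basis]][[paste0("wave_", w)]] <- list(
          linear = fit_cumulative_effect(d$E, d$sr, FALSE, config),
          quadratic = fit_cumulative_effect(d$E, d$sr, TRUE, config))
      }
    }
    note(paste0("cumulative_", basis), nrow(merge(base1, srw(2), by = "participant_id")))

    for (rf_name in c("support", "trust", "rec")) {
      for (w in 1:3) {
        d <- merge(base1[c("participant_id", rf_name, "age", "gender")],
                   srw(w), by = "participant_id")
        d <- d[!is.na(d[[rf_name]]) & !is.na(d$sr), , drop = FALSE]
        if (nrow(d) < 10) next
        un <- fit_rf_association(d[[rf_name]], d$sr, FALSE, config = config)
        ad <- fit_rf_association(d[[rf_name]], d$sr, TRUE, age = d$age,
                                 gender = d$gender, config = config)
        key <- paste(basis, rf_name, w, sep = ".")
        out$rf_fits[[key]] <- list(unadjusted = un, adjusted = ad)
        rf_rows[[key]] <- data.frame(
          basis = basis, factor = rf_name, wave = w, n = un$n,
          B = reg_estimate(un, "rf")$estimate,
          ci_low = reg_estimate(un, "rf")$ci_low,
          ci_high = reg_estimate(un, "rf")$ci_high,
          B_adj = reg_estimate(ad, "rf")$estimate,
          ci_low_adj = reg_estimate(ad, "rf")$ci_low,
          ci_high_adj = reg_estimate(ad, "rf")$ci_high)
      }
    }
    note(paste0("rf_grid_", basis), length(rf_rows))

    for (w in 2:3) {
      d <- merge(base1[c("participant_id", "support", "trust", "rec", "E")],
                 srw(w), by = "participant_id")
      d <- d[stats::complete.cases(d[-1]), , drop = FALSE]
      if (nrow(d) >= 20) {
        out$multivariate[[basis]][[paste0("wave_", w)]] <-
          fit_multivariate(d$support, d$trust, d$rec, d$E, d$sr, config)
      }
    }

    for (rf_name in c("support", "trust", "rec")) {
      d <- merge(base1[c("participant_id", rf_name, "E")], srw(2),
                 by = "participant_id")
      d <- d[stats::complete.cases(d[-1]), , drop = FALSE]
      if (nrow(d) < 20) next
      mod <- fit_moderation(d[[rf_name]], d$E, d$sr, config)
      out$moderation[[basis]][[rf_name]] <- mod
      out$simple_slopes[[basis]][[rf_name]] <- simple_slopes(mod, e_mean, e_sd)
    }
    note(paste0("moderation_", basis), length(out$moderation[[basis]]))

    d <- merge(base1[c("participant_id", "support", "rec")], srw(1),
               by = "participant_id")
    d <- d[stats::complete.cases(d[-1]), , drop = FALSE]
    if (nrow(d) >= 10) {
      out$mediation[[basis]] <- withCallingHandlers(
        bootstrap_indirect(d$support, d$rec, d$sr, config = config),
        warning = function(w) invokeRestart("muffleWarning"))
    }
    note(paste0("mediation_", basis), nrow(d))

    ## sensitivity: complete-case re-run of the resilience-factor grid
    cc <- tryCatch(complete_case_subset(cohort, c("E", p_var), config),
                   error = function(e) NULL)
    if (!is.null(cc)) {
      cc_pooled <- sr_fit(cc, basis, "pooled_complete_cases", config)
      sccw <- cc_pooled$scores
      sccw$sr <- if (config$standardise_sr) sccw$standardised else sccw$raw
      cc_base <- score_cohort(cc, config)
      cc_base <- cc_base[cc_base$wave == 1, , drop = FALSE]
      sens <- list()
      for (rf_name in c("support", "trust", "rec")) {
        d <- merge(cc_base[c("participant_id", rf_name)],
                   sccw[sccw$wave == 2, c("participant_id", "sr")],
                   by = "participant_id")
        d <- d[stats::complete.cases(d[-1]), , drop = FALSE]
        if (nrow(d) >= 10 && stats::sd(d[[rf_name]]) > 0) {
          sens[[rf_name]] <- fit_rf_association(d[[rf_name]], d$sr, FALSE,
                                                config = config)
        }
      }
      out$sensitivity[[basis]] <- sens
      note(paste0("sensitivity_", basis), if (length(sens)) sens[[1]]$n else 0)
    }
  }

  out$rf_grid <- if (length(rf_rows)) do.call(rbind, rf_rows) else NULL
  if (!is.null(out$rf_grid)) rownames(out$rf_grid) <- NULL
  out$log <- do.call(rbind, log)
  out$meta <- list(seed = config$rng_seed, bases = bases,
                   standardise_sr = config$standardise_sr,
                   n_bootstrap = config$n_bootstrap,
                   package_version = as.character(utils::packageVersion("srscore")),
                   config_hash = config_hash(config))
  structure(out, class = "sr_report")
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  ## small rolling hash; enough to detect config drift between runs
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%x", h)
}

#' @export
print.sr_report <- function(x, ...) {
  cat("srscore pipeline report\n")
  cat(sprintf("  observations: %d; seed %d; config %s\n", x$cohort_n,
              x$meta$seed, x$meta$config_hash))
  cat("  stages:\n")
  for (i in seq_len(nrow(x$log))) {
    cat(sprintf("    %-16s n = %d\n", x$log$stage[i], x$log$n[i]))
  }
  invisible(x)
}

#' Write the report bundle to a directory
#'
#' Emits tidy CSV tables (reliability, descriptives, SR scores, association
#' grid), JSON metadata (normative lines, mediation, run manifest) and SVG
#' moderation plots.
#'
#' @param report An `sr_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$reliability, file.path(dir, "reliability.csv"),
                   row.names = FALSE)
  utils::write.csv(report$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  if (!is.null(report$rf_grid)) {
    utils::write.csv(report$rf_grid, file.path(dir, "rf_associations.csv"),
                     row.names = FALSE)
  }
  for (basis in names(report$sr)) {
    utils::write.csv(report$sr[[basis]]$per_wave$scores,
                     file.path(dir, paste0("sr_", basis, ".csv")),
                     row.names = FALSE)
    lines <- lapply(report$sr[[basis]]$per_wave$lines, function(l) {
      list(degree = l$degree, coefficients = as.list(l$coefficients),
           n = l$n, rss = l$rss, scope = l$scope)
    })
    writeLines(jsonlite::toJSON(lines, auto_unbox = TRUE, digits = NA),
               file.path(dir, paste0("normative_", basis, ".json")))
    if (!is.null(report$mediation[[basis]])) {
      writeLines(mediation_json(report$mediation[[basis]]),
                 file.path(dir, paste0("mediation_", basis, ".json")))
    }
    for (rf_name in names(report$simple_slopes[[basis]])) {
      f <- file.path(dir, sprintf("moderation_%s_%s.svg", basis, rf_name))
      grDevices::svg(f, width = 6, height = 4.5)
      plot_simple_slopes(report$simple_slopes[[basis]][[rf_name]],
                         report$moderation[[basis]][[rf_name]],
                         main = sprintf("%s x baseline E (%s)", rf_name, basis))
      grDevices::dev.off()
    }
  }
  manifest <- list(meta = report$meta,
                   log = lapply(seq_len(nrow(report$log)), function(i)
                     as.list(report$log[i, ])))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

plot_simple_slopes <- function(ss, mod, main = "") {
  b <- coef(mod)
  rf_grid <- seq(1, 5, length.out = 50)
  levels_m <- ss$slopes$moderator_value[c(1, 3)]
  cols <- c("goldenrod2", "purple3")
  y <- sapply(levels_m, function(m)
    b[["(Intercept)"]] + b[["rf"]] * rf_grid + b[["E"]] * m +
      b[[grep(":", names(b), value = TRUE)]] * rf_grid * m)
  graphics::matplot(rf_grid, y, type = "l", lty = 1, lwd = 2, col = cols,
                    xlab = "Resilience factor (baseline)", ylab = "SR score",
                    main = main)
  graphics::legend("topright", c("E: mean - SD", "E: mean + SD"),
                   col = cols, lwd = 2, bty = "n")
}
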