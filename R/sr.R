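#' Fit the normative E-P line
#'
#' Ordinary least-squares polynomial regression of mental-health problems (P)
#' on stressor exposure (E), degree 1 (linear) or 2 (quadratic). The fitted
#' line is the sample's normative stressor reactivity: it gives the expected P
#' at each level of E, and individual residuals from it are SR scores.
#'
#' @param E Exposure scores (percent, 0-100).
#' @param P Symptom totals (PHQ-9 or GHQ-12 points).
#' @param degree 1 or 2.
#' @param scope Label for the fit sample, e.g. `"pooled_complete_cases"` or
#'   `"wave_1"`.
#' @param basis `"dep"` (PHQ-9) or `"dis"` (GHQ-12).
#' @return An object of class `normative_line`: coefficients (beta0, beta1 per
#'   percent, beta2 per percent squared when quadratic), `degree`, `scope`,
#'   `basis`, `n`, `rss`, and the underlying `lm` fit.
#' @export
fit_normative_line <- function(E, P, degree = 1L, scope = "pooled_complete_cases",
                               basis = c("dep", "dis")) {
  basis <- match.arg(basis)
  degree <- as.integer(degree)
  stopifnot(degree %in% c(1L, 2L))
  keep <- !is.na(E) & !is.na(P)
  E <- E[keep]; P <- P[keep]
  n <- length(E)
  if (n <= degree + 1L) {
    stop(sprintf("sample-size error: n = %d too small for degree-%d fit", n, degree),
         call. = FALSE)
  }
  if (stats::sd(E) == 0) {
    stop("singular-design error: exposure is constant in the fit sample", call. = FALSE)
  }
  dat <- data.frame(P = P, E = E)
  fit <- if (degree == 1L) stats::lm(P ~ E, data = dat)
         else stats::lm(P ~ E + I(E^2), data = dat)
  rss <- sum(stats::residuals(fit)^2)
  co <- stats::coef(fit)
  names(co) <- c("beta0", "beta1", "beta2")[seq_along(co)]
  structure(
    list(coefficients = co, degree = degree, scope = scope, basis = basis,
         n = n, rss = rss, fit = fit),
    class = "normative_line"
  )
}

#' @export
print.normative_line <- function(x, ...) {
  cat(sprintf("Normative E-P line (%s, %s): degree %d, n = %d, rss = %.2f\n",
              x$basis, x$scope, x$degree, x$n, x$rss))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
predict.normative_line <- function(object, newdata, ...) {
  E <- if (is.data.frame(newdata)) newdata$E else as.numeric(newdata)
  co <- object$coefficients
  out <- co[["beta0"]] + co[["beta1"]] * E
  if (object$degree == 2L) out <- out + co[["beta2"]] * E^2
  unname(out)
}

#' Choose the polynomial degree of the normative line
#'
#' Compares the linear and quadratic fits with a chi-squared (likelihood-ratio)
#' test for nested Gaussian OLS models: statistic n log(rss1 / rss2) on 1
#' degree of freedom. Degree 2 is selected when p < the configured
#' significance level.
#'
#' @inheritParams fit_normative_line
#' @param config An [sr_config()].
#' @return A list: `degree`, `statistic`, `df`, `p`, and both candidate
#'   `normative_line` fits.
#' @export
select_degree <- function(E, P, config = NULL, scope = "pooled_complete_cases",
                          basis = "dep") {
  config <- as_sr_config(config)
  l1 <- fit_normative_line(E, P, 1L, scope, basis)
  l2 <- fit_normative_line(E, P, 2L, scope, basis)
  stat <- l1$n * log(l1$rss / l2$rss)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  degree <- if (p < config$significance_level) 2L else 1L
  list(degree = degree, statistic = stat, df = 1L, p = p,
       linear = l1, quadratic = l2)
}

#' Stressor reactivity scores from a cohort
#'
#' The central estimator. Computes E and P for every observation, fits the
#' normative E-P line (pooled over the three waves of the complete-case
#' sample, or separately per cross-sectional wave), selects the polynomial
#' degree per line with [select_degree()], and scores each individual's
#' stressor reactivity as the residual of observed P from the line. Negative
#' SR = fewer problems than normatively expected for the exposure faced (a
#' resilient outcome); positive SR = an over-reaction.
#'
#' @param cohort A [cohort_table()].
#' @param basis `"dep"` (P = PHQ-9 total) or `"dis"` (P = GHQ-12 total).
#' @param mode `"pooled_complete_cases"`: one line on all rows of the
#'   complete-case sample (participants with E and P at all three waves), used
#'   for longitudinal comparison. `"per_wave"`: one line per wave on all rows
#'   with E and P at that wave (full sample), used for the cross-sectional
#'   analyses.
#' @param config An [sr_config()]; `standardise_sr` controls whether the
#'   standardised score (raw residual / SD of residuals within the fit scope)
#'   is populated.
#' @param min_n Waves with fewer rows are skipped with a warning (per-wave
#'   mode only).
#' @return An object of class `sr_fit` with components `scores` (data.frame:
#'   `participant_id`, `wave`, `basis`, `E`, `P`, `raw`, `standardised`,
#'   `degree`, `scope`), `lines` (list of `normative_line`), `mode`, `basis`,
#'   `config`. Methods: `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `fitted`, `plot`.
#' @export
sr_fit <- function(cohort, basis = c("dep", "dis"),
                   mode = c("pooled_complete_cases", "per_wave"),
                   config = NULL, min_n = 10L) {
  stopifnot(inherits(cohort, "cohort_table"))
  basis <- match.arg(basis)
  mode <- match.arg(mode)
  config <- as_sr_config(config)
  p_var <- if (basis == "dep") "phq9" else "ghq12"

  if (mode == "pooled_complete_cases") {
    cc <- complete_case_subset(cohort, c("E", p_var), config)
    sc <- score_cohort(cc, config)
    sc$P <- sc[[p_var]]
    sel <- select_degree(sc$E, sc$P, config, scope = "pooled_complete_cases",
                         basis = basis)
    line <- if (sel$degree == 2L) sel$quadratic else sel$linear
    line$selection <- sel[c("statistic", "df", "p", "degree")]
    scores <- sr_residuals_for(sc, line, config, scope = "pooled_complete_cases")
    lines <- list(pooled_complete_cases = line)
  } else {
    sc_all <- score_cohort(cohort, config)
    sc_all$P <- sc_all[[p_var]]
    lines <- list()
    scores_list <- list()
    for (w in sort(unique(sc_all$wave))) {
      sw <- sc_all[sc_all$wave == w & !is.na(sc_all$E) & !is.na(sc_all$P), ,
                   drop = FALSE]
      if (nrow(sw) < min_n) {
        warning(sprintf("wave %d skipped: only %d rows with E and P", w, nrow(sw)))
        next
      }
      scope <- paste0("wave_", w)
      sel <- select_degree(sw$E, sw$P, config, scope = scope, basis = basis)
      line <- if (sel$degree == 2L) sel$quadratic else sel$linear
      line$selection <- sel[c("statistic", "df", "p", "degree")]
      lines[[scope]] <- line
      scores_list[[scope]] <- sr_residuals_for(sw, line, config, scope = scope)
    }
    if (!length(lines)) stop("sample-size error: no wave had enough rows", call. = FALSE)
    scores <- do.call(rbind, scores_list)
    rownames(scores) <- NULL
  }

  structure(
    list(scores = scores, lines = lines, mode = mode, basis = basis,
         config = config),
    class = "sr_fit"
  )
}

sr_residuals_for <- function(sc, line, config, scope) {
  keep <- !is.na(sc$E) & !is.na(sc$P)
  sc <- sc[keep, , drop = FALSE]
  expected <- predict.normative_line(line, sc$E)
  raw <- sc$P - expected
  sd_raw <- stats::sd(raw)
  standardised <- if (config$standardise_sr && sd_raw > 0) raw / sd_raw
                  else rep(NA_real_, length(raw))
  data.frame(
    participant_id = sc$participant_id, wave = sc$wave,
    basis = line$basis, E = sc$E, P = sc$P,
    raw = raw, standardised = standardised,
    degree = line$degree, scope = scope,
    stringsAsFactors = FALSE
  )
}

#' @export
print.sr_fit <- function(x, ...) {
  cat(sprintf("Stressor reactivity fit: basis = %s, mode = %s\n", x$basis, x$mode))
  for (nm in names(x$lines)) {
    l <- x$lines[[nm]]
    cat(sprintf("  %s: degree %d (LRT p = %.3g), n = %d\n",
                nm, l$degree, l$selection$p, l$n))
  }
  cat(sprintf("  %d SR scores computed\n", nrow(x$scores)))
  invisible(x)
}

#' @export
summary.sr_fit <- function(object, ...) {
  s <- object$scores
  agg <- do.call(rbind, lapply(split(s, list(s$scope, s$wave), drop = TRUE),
    function(d) data.frame(scope = d$scope[1], wave = d$wave[1], n = nrow(d),
                           raw_mean = mean(d$raw), raw_sd = stats::sd(d$raw))))
  rownames(agg) <- NULL
  agg[order(agg$scope, agg$wave), ]
}

#' @export
coef.sr_fit <- function(object, ...) {
  lapply(object$lines, function(l) l$coefficients)
}

#' Expected P at given exposure levels
#'
#' @param object An [sr_fit()].
#' @param newdata Data.frame with column `E` (and `wave` in per-wave mode) or
#'   a numeric vector of E values (pooled mode).
#' @param ... Unused.
#' @export
predict.sr_fit <- function(object, newdata, ...) {
  if (object$mode == "pooled_complete_cases") {
    return(predict.normative_line(object$lines[[1]], newdata))
  }
  stopifnot(is.data.frame(newdata), all(c("E", "wave") %in% names(newdata)))
  out <- rep(NA_real_, nrow(newdata))
  for (w in unique(newdata$wave)) {
    scope <- paste0("wave_", w)
    if (is.null(object$lines[[scope]])) next
    idx <- newdata$wave == w
    out[idx] <- predict.normative_line(object$lines[[scope]], newdata$E[idx])
  }
  out
}

#' @export
residuals.sr_fit <- function(object, type = c("raw", "standardised"), ...) {
  type <- match.arg(type)
  object$scores[[type]]
}

#' @export
fitted.sr_fit <- function(object, ...) {
  object$scores$P - object$scores$raw
}

#' Plot the normative line(s) with the observed E-P cloud
#'
#' @param x An [sr_fit()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sr_fit <- function(x, ...) {
  s <- x$scores
  graphics::plot(s$E, s$P, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("grey40", 0.5),
                 xlab = "Stressor exposure E (%)",
                 ylab = if (x$basis == "dep") "PHQ-9 total" else "GHQ-12 total",
                 ...)
  grid_E <- seq(0, 100, length.out = 200)
  cols <- c("firebrick", "steelblue", "darkgreen")
  i <- 0
  for (nm in names(x$lines)) {
    i <- i + 1
    graphics::lines(grid_E, predict.normative_line(x$lines[[nm]], grid_E),
                    col = cols[(i - 1) %% 3 + 1], lwd = 2)
  }
  graphics::legend("topleft", legend = names(x$lines),
                   col = cols[seq_along(x$lines)], lwd = 2, bty = "n")
  invisible(x)
}

#' SR scores as a tidy table
#'
#' @param fit An [sr_fit()].
#' @return The `scores` data.frame.
#' @export
sr_scores <- function(fit) {
  stopifnot(inherits(fit, "sr_fit"))
  fit$scores
}
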