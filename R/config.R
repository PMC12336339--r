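#' Analysis configuration
#'
#' Bundles the knobs shared across the analysis chain.
#'
#' @param significance_level Two-sided alpha used for CIs and for the
#'   linear-vs-quadratic degree selection test. Default 0.05.
#' @param n_bootstrap Bootstrap iterations for the mediation indirect effect.
#'   Default 5000.
#' @param rng_seed Integer seed routed to every stochastic step.
#' @param standardise_sr If `TRUE` (default) SR scores are z-standardised
#'   within their fit scope; raw residuals are always retained alongside.
#' @param min_item_coverage Minimum fraction of administered stressor items
#'   that must be answered for an exposure score to be computed; below it the
#'   score is missing. Default 0.8.
#' @param impute_unanswered If `TRUE`, unanswered stressor items are treated as
#'   "did not occur" and the denominator is the full administered battery.
#'   Default `FALSE` (denominator = items answered).
#'
#' @return An object of class `sr_config`.
#' @export
sr_config <- function(significance_level = 0.05,
                      n_bootstrap = 5000L,
                      rng_seed = 1L,
                      standardise_sr = TRUE,
                      min_item_coverage = 0.8,
                      impute_unanswered = FALSE) {
  if (!(significance_level > 0 && significance_level < 1)) {
    stop("significance_level must lie in (0, 1)", call. = FALSE)
  }
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1", call. = FALSE)
  if (!(min_item_coverage > 0 && min_item_coverage <= 1)) {
    stop("min_item_coverage must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      significance_level = significance_level,
      n_bootstrap = as.integer(n_bootstrap),
      rng_seed = as.integer(rng_seed),
      standardise_sr = isTRUE(standardise_sr),
      min_item_coverage = min_item_coverage,
      impute_unanswered = isTRUE(impute_unanswered)
    ),
    class = "sr_config"
  )
}

as_sr_config <- function(config) {
  if (is.null(config)) return(sr_config())
  stopifnot(inherits(config, "sr_config"))
  config
}
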