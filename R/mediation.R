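## Baron-Kenny mediation: support from colleagues (x) -> REC (m) -> SR (y).
## Three OLS fits on one identical row set:
##   (i)   y ~ x (+ cov):        total effect c
##   (ii)  m ~ x (+ cov):        path a
##   (iii) y ~ x + m (+ cov):    direct effect c' and path b
## For linear OLS on a common row set the identity c = c' + a*b holds exactly.

## Fast OLS coefficient solver used inside the bootstrap loop.
ols_coef <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  if (fit$rank < ncol(X)) return(NULL)  # singular design
  fit$coefficients
}

mediation_design <- function(x, m, y, covariates = NULL) {
  d <- data.frame(x = x, m = m, y = y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(x))
    d <- cbind(d, covariates)
  }
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 10L) stop("sample-size error: fewer than 10 complete rows", call. = FALSE)
  if (stats::sd(d$x) == 0 || stats::sd(d$m) == 0) {
    stop("singular-design error: constant exposure or mediator", call. = FALSE)
  }
  Z <- if (ncol(d) > 3L) {
    stats::model.matrix(~ ., data = d[, -(1:3), drop = FALSE])[, -1, drop = FALSE]
  } else NULL
  list(d = d, Z = Z)
}

## Design matrices built once; bootstrap replicates subset rows.
mediation_mats <- function(d, Z) {
  one <- rep(1, nrow(d))
  Xc <- cbind(`(Intercept)` = one, x = d$x)
  if (!is.null(Z)) Xc <- cbind(Xc, Z)
  Xm <- cbind(Xc[, 1:2, drop = FALSE], m = d$m)
  if (!is.null(Z)) Xm <- cbind(Xm, Z)
  list(Xc = Xc, Xm = Xm, y = d$y, m = d$m)
}

paths_from_mats <- function(mats) {
  co_c <- ols_coef(mats$Xc, mats$y)
  co_a <- ols_coef(mats$Xc, mats$m)
  co_b <- ols_coef(mats$Xm, mats$y)
  if (is.null(co_c) || is.null(co_a) || is.null(co_b)) return(NULL)
  c(a = co_a[2], b = co_b[3], c = co_c[2], c_prime = co_b[2])
}

subset_mats <- function(mats, idx) {
  list(Xc = mats$Xc[idx, , drop = FALSE], Xm = mats$Xm[idx, , drop = FALSE],
       y = mats$y[idx], m = mats$m[idx])
}

mediation_paths <- function(d, Z) {
  paths_from_mats(mediation_mats(d, Z))
}

#' Pre-check: exposure x mediator interaction
#'
#' The product-term check behind the no-interaction assumption of the
#' Baron-Kenny decomposition: fits `y ~ x + m + x:m` and reports the
#' interaction coefficient and p-value. A significant interaction raises a
#' warning (the pipeline does not abort).
#'
#' @param x Exposure (support from colleagues).
#' @param m Mediator (REC).
#' @param y Outcome (SR score).
#' @param config An [sr_config()].
#' @return List: `estimate`, `se`, `p`, `n`, `warned`.
#' @export
check_xm_interaction <- function(x, m, y, config = NULL) {
  config <- as_sr_config(config)
  des <- mediation_design(x, m, y)
  d <- des$d
  fit <- stats::lm(y ~ x * m, data = d)
  co <- summary(fit)$coefficients
  est <- co["x:m", 1]; se <- co["x:m", 2]; p <- co["x:m", 4]
  warned <- p < config$significance_level
  if (warned) {
    warning(sprintf(
      "exposure x mediator interaction detected (p = %.3g); Baron-Kenny paths may be misleading",
      p))
  }
  list(estimate = est, se = se, p = p, n = nrow(d), warned = warned)
}

#' Baron-Kenny mediation point estimates
#'
#' @inheritParams check_xm_interaction
#' @param covariates Optional data.frame of covariates included symmetrically
#'   in all three regressions (default none, matching unadjusted reporting).
#' @return An object of class `sr_mediation` with paths `a`, `b`, `c`,
#'   `c_prime`, the product-of-paths `indirect` point estimate, and `n`. The
#'   identity `c = c_prime + a*b` is verified internally.
#' @export
baron_kenny <- function(x, m, y, covariates = NULL, config = NULL) {
  config <- as_sr_config(config)
  des <- mediation_design(x, m, y, covariates)
  paths <- mediation_paths(des$d, des$Z)
  if (is.null(paths)) stop("singular-design error in mediation fit", call. = FALSE)
  gap <- paths[["c"]] - (paths[["c_prime"]] + paths[["a"]] * paths[["b"]])
  if (abs(gap) > 1e-8) {
    stop("integrity error: c != c' + a*b; row sets diverged between fits", call. = FALSE)
  }
  structure(
    list(a = paths[["a"]], b = paths[["b"]], c = paths[["c"]],
         c_prime = paths[["c_prime"]],
         indirect = paths[["a"]] * paths[["b"]],
         n = nrow(des$d), covariates = !is.null(covariates)),
    class = "sr_mediation"
  )
}

#' Bootstrapped indirect effect
#'
#' Case-resampling bootstrap (whole rows, preserving the joint x-m-y
#' distribution) of the product of paths a*b. Reports the mean bootstrapped
#' indirect effect and a percentile confidence interval (BCa optional).
#' Replicates with a singular design are redrawn and counted. Fully
#' reproducible under `config$rng_seed`.
#'
#' @inheritParams baron_kenny
#' @param ci_type `"percentile"` (default) or `"bca"`.
#' @return An `sr_mediation` augmented with `indirect_boot_mean`, `ci_low`,
#'   `ci_high`, `n_boot`, `seed`, `n_redrawn`, `interaction_check`.
#' @export
bootstrap_indirect <- function(x, m, y, covariates = NULL, config = NULL,
                               ci_type = c("percentile", "bca")) {
  config <- as_sr_config(config)
  ci_type <- match.arg(ci_type)
  base <- baron_kenny(x, m, y, covariates, config)
  inter <- withCallingHandlers(
    check_xm_interaction(x, m, y, config),
    warning = function(w) invokeRestart("muffleWarning")
  )
  des <- mediation_design(x, m, y, covariates)
  mats <- mediation_mats(des$d, des$Z)
  n <- nrow(des$d)
  B <- config$n_bootstrap
  draws <- numeric(B)
  n_redrawn <- 0L
  old_seed <- set_local_seed(config$rng_seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  for (i in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      paths <- paths_from_mats(subset_mats(mats, idx))
      if (!is.null(paths)) break
      n_redrawn <- n_redrawn + 1L
    }
    draws[i] <- paths[["a"]] * paths[["b"]]
  }
  a2 <- config$significance_level / 2
  if (ci_type == "percentile") {
    ci <- unname(stats::quantile(draws, c(a2, 1 - a2), type = 7))
  } else {
    z0 <- stats::qnorm(mean(draws < base$indirect))
    jk <- vapply(seq_len(n), function(i) {
      p <- paths_from_mats(subset_mats(mats, -i))
      p[["a"]] * p[["b"]]
    }, numeric(1))
    u <- mean(jk) - jk
    acc <- sum(u^3) / (6 * sum(u^2)^1.5)
    za <- stats::qnorm(c(a2, 1 - a2))
    probs <- stats::pnorm(z0 + (z0 + za) / (1 - acc * (z0 + za)))
    ci <- unname(stats::quantile(draws, probs, type = 7))
  }
  out <- base
  out$indirect_boot_mean <- mean(draws)
  out$ci_low <- ci[1]
  out$ci_high <- ci[2]
  out$n_boot <- B
  out$seed <- config$rng_seed
  out$n_redrawn <- n_redrawn
  out$ci_type <- ci_type
  out$interaction_check <- inter
  out
}

#' @export
print.sr_mediation <- function(x, digits = 4, ...) {
  cat("Baron-Kenny mediation (x -> m -> y)\n")
  cat(sprintf("  a = %.*f, b = %.*f, c = %.*f, c' = %.*f  (n = %d)\n",
              digits, x$a, digits, x$b, digits, x$c, digits, x$c_prime, x$n))
  cat(sprintf("  indirect a*b = %.*f\n", digits, x$indirect))
  if (!is.null(x$n_boot)) {
    cat(sprintf("  mean bootstrapped indirect = %.*f, 95%% CI (%.*f, %.*f), %d iterations, seed %d\n",
                digits, x$indirect_boot_mean, digits, x$ci_low, digits, x$ci_high,
                x$n_boot, x$seed))
    ic <- x$interaction_check
    cat(sprintf("  x:m interaction pre-check: estimate %.*f, p = %.3g\n",
                digits, ic$estimate, ic$p))
  }
  invisible(x)
}

#' Serialise a mediation result as JSON
#'
#' @param x An `sr_mediation`.
#' @return A JSON string.
#' @export
mediation_json <- function(x) {
  stopifnot(inherits(x, "sr_mediation"))
  keep <- intersect(c("a", "b", "c", "c_prime", "indirect", "indirect_boot_mean",
                      "ci_low", "ci_high", "n", "n_boot", "seed", "n_redrawn",
                      "ci_type"), names(x))
  jsonlite::toJSON(x[keep], auto_unbox = TRUE, digits = NA)
}

## Seed scoping: route all randomness through an explicit seed without
## clobbering the caller's RNG state.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
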