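## Synthetic multi-wave cohort generator.
##
## Item model: within each scale, item latents are compound symmetric around a
## person (x wave) factor theta and are discretised by thresholds shared across
## the scale's items. Thresholds, inter-item correlations and structural
## conversion constants are produced by the moment-matching routine
## calibrate_generator() (see calibration.R) and shipped frozen in constants.R.
##
## Structural scale conventions:
##   * normative slope/curvature: symptom points per percent E (and percent^2);
##   * resilience-factor paths, moderation, cumulative carry-over: standardised
##     SR units per observed unit of the predictor. Ordinal discretisation
##     attenuates latent effects, so the calibration measures the attenuation
##     with probe regressions and the generator compensates, making configured
##     truths recoverable by OLS on the observed scale.

#' Invert Cronbach's alpha to an inter-item correlation
#'
#' Under exchangeable (compound-symmetric) items, alpha = k r / (1 + (k-1) r);
#' this returns the exact inversion r = alpha / (k - (k-1) alpha), used as the
#' starting point when calibrating latent item blocks.
#'
#' @param target_alpha Desired alpha in (0, 1).
#' @param k Number of items (>= 2).
#' @return The inter-item correlation r.
#' @export
#' @examples
#' calibrate_scale_correlation(0.80, 6)  # 0.4
calibrate_scale_correlation <- function(target_alpha, k) {
  if (!(target_alpha > 0 && target_alpha < 1)) {
    stop("domain error: target_alpha must lie in (0, 1)", call. = FALSE)
  }
  if (k < 2) stop("domain error: k must be >= 2", call. = FALSE)
  target_alpha / (k - (k - 1) * target_alpha)
}

#' Synthetic-cohort generator configuration
#'
#' Defaults describe the study conditions the generator emulates: a three-wave
#' healthcare-worker cohort with 2,422 baseline respondents, dropout and new
#' entrants, declining exposure across waves, item blocks calibrated to the
#' printed baseline moments and reliabilities, a stable per-person reactivity
#' component, resilience factors with a built-in support -> REC -> SR mediation
#' path, exposure-moderated effects and a cumulative baseline-exposure
#' carry-over.
#'
#' @param n_wave1 Baseline sample size.
#' @param retention Continuation probabilities `c(w1_to_w2, w2_to_w3)`.
#' @param new_entrants New respondents entering at waves 2 and 3.
#' @param exposure_mean Target mean E (percent) per wave; declining by default.
#' @param exposure_sd Target SD of baseline E (percent).
#' @param exposure_autocorr Within-person correlation of the latent exposure
#'   propensity across waves.
#' @param support_trust_cor Latent correlation between the support and trust
#'   single items.
#' @param rf_paths List: `a` (support -> REC, REC points per support point),
#'   `b` (REC -> SR, standardised-SR units per REC point, controlling support),
#'   `c_prime` (direct support -> SR), `trust` (trust -> SR).
#' @param moderation List of factor x baseline-E interaction coefficients
#'   (standardised-SR per factor point per percent): `support`, `trust`,
#'   `rec_dep`, `rec_dis`.
#' @param cumulative_effect Baseline-E carry-over onto waves 2-3 SR
#'   (standardised-SR per percent).
#' @param reactivity_share Share of the non-exposure SR variance carried by the
#'   stable per-person reactivity intercept.
#' @param distress_share Correlation of the dep and dis non-exposure residual
#'   components (calibrated default reproduces the observed wave-1
#'   SR_dep-SR_dis correlation).
#' @param residual_noise_scale Multiplier on the residual (non-structural)
#'   distress component; 0 gives a near-deterministic E-P relation.
#' @param covariates List: `age_mean`, `age_sd`, `p_female`, `p_gender_unknown`.
#' @param missingness Per-wave block missingness rates: a list with numeric
#'   length-3 vectors `stressors`, `phq9`, `ghq12`, `rec`, `support`, `trust`,
#'   `age`. Missingness is completely at random by default.
#' @param item_missing Per-cell missingness rate for answered stressor blocks.
#' @param dropout_distress_weight Optional logistic weight making dropout
#'   depend on current distress (0 = missing completely at random).
#' @param bank A [stressor_bank()] (availability mask per wave).
#' @param calibration Calibration constants, as produced by
#'   [calibrate_generator()]; defaults to the packaged constants.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_wave1 = 2422L,
                             retention = c(0.50, 0.274),
                             new_entrants = c(616L, 34L),
                             exposure_mean = c(39, 34, 30),
                             exposure_sd = 15,
                             exposure_autocorr = 0.5,
                             support_trust_cor = 0.3,
                             rf_paths = list(a = 0.12, b = -0.45,
                                             c_prime = -0.15, trust = -0.10),
                             moderation = list(support = 0, trust = -0.003,
                                               rec_dep = 0, rec_dis = 0.004),
                             cumulative_effect = 0.01,
                             reactivity_share = 0.4,
                             distress_share = NULL,
                             residual_noise_scale = 1,
                             covariates = list(age_mean = 43, age_sd = 12,
                                               p_female = 0.78,
                                               p_gender_unknown = 0.015),
                             missingness = list(
                               stressors = c(0.065, 0.03, 0.03),
                               phq9 = c(0.227, 0.11, 0.11),
                               ghq12 = c(0.199, 0.10, 0.10),
                               rec = c(0.237, 0.12, 0.12),
                               support = c(0.227, 0.11, 0.11),
                               trust = c(0.116, 0.06, 0.06),
                               age = c(0.04, 0.04, 0.04)
                             ),
                             item_missing = 0.01,
                             dropout_distress_weight = 0,
                             bank = stressor_bank(),
                             calibration = NULL) {
  if (is.null(calibration)) calibration <- srscore_calibration()
  if (is.null(distress_share)) distress_share <- calibration$struct$distress_share
  stopifnot(all(retention >= 0 & retention <= 1),
            reactivity_share >= 0, reactivity_share <= 1,
            distress_share >= 0, distress_share < 1,
            exposure_autocorr >= 0, exposure_autocorr < 1)
  structure(
    list(n_wave1 = as.integer(n_wave1), retention = retention,
         new_entrants = as.integer(new_entrants),
         exposure_mean = exposure_mean, exposure_sd = exposure_sd,
         exposure_autocorr = exposure_autocorr,
         support_trust_cor = support_trust_cor,
         rf_paths = rf_paths, moderation = moderation,
         cumulative_effect = cumulative_effect,
         reactivity_share = reactivity_share,
         distress_share = distress_share,
         residual_noise_scale = residual_noise_scale,
         covariates = covariates, missingness = missingness,
         item_missing = item_missing,
         dropout_distress_weight = dropout_distress_weight,
         bank = bank, calibration = calibration),
    class = "generator_config"
  )
}

#' Default (calibrated) generator configuration
#'
#' @return A [generator_config()] whose generated baseline cohort matches the
#'   calibration targets (baseline moments, scale reliabilities, wave-1 E-P
#'   correlations, wave-1 SR_dep-SR_dis correlation, probable-MDD proportion)
#'   within Monte-Carlo tolerance.
#' @export
default_config <- function() {
  generator_config()
}

## Standardised skew-normal draws (zero mean, unit variance, shape delta).
rskewnorm <- function(n, delta) {
  if (delta == 0) return(stats::rnorm(n))
  x <- delta * abs(stats::rnorm(n)) + sqrt(1 - delta^2) * stats::rnorm(n)
  mu <- delta * sqrt(2 / pi)
  (x - mu) / sqrt(1 - mu^2)
}

## Discretise a latent matrix/vector with shared thresholds: score = number of
## thresholds exceeded (0..length(t)).
cut_latent <- function(y, thresholds) {
  s <- 0L
  for (t in thresholds) s <- s + (y > t)
  s
}

## Item block: n x k latents, compound-symmetric around theta with loading
## sqrt(rho), discretised by shared thresholds.
draw_item_block <- function(theta, k, rho, thresholds) {
  n <- length(theta)
  y <- sqrt(rho) * theta + sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
  cut_latent(y, thresholds)
}

#' Generate a synthetic multi-wave cohort
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; identical config + seed gives an identical cohort.
#' @param keep_latents Attach the wave-1 standardised person factors as an
#'   attribute `"latents"` (used by the calibration routine).
#' @return A [cohort_table()].
#' @export
generate_cohort <- function(config = default_config(), seed = 1L,
                            keep_latents = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  cal <- config$calibration
  st <- cal$struct
  bank <- config$bank

  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)

  n1 <- config$n_wave1
  e2 <- config$new_entrants[1]
  e3 <- config$new_entrants[2]
  N <- n1 + e2 + e3
  entry <- rep(1:3, times = c(n1, e2, e3))
  id <- sprintf("P%06d", seq_len(N))

  cov <- config$covariates
  age <- pmin(pmax(round(stats::rnorm(N, cov$age_mean, cov$age_sd)), 18), 75)
  gender <- sample(c("female", "male", "unknown"), N, replace = TRUE,
                   prob = c(cov$p_female * (1 - cov$p_gender_unknown),
                            (1 - cov$p_female) * (1 - cov$p_gender_unknown),
                            cov$p_gender_unknown))

  ## person-level latents
  S_lat <- stats::rnorm(N)
  r_st <- config$support_trust_cor
  T_lat <- r_st * S_lat + sqrt(1 - r_st^2) * stats::rnorm(N)
  R0 <- stats::rnorm(N)
  Xp <- stats::rnorm(N)

  sup_obs <- 1L + cut_latent(S_lat, cal$support$thresholds)
  trust_obs <- cut_latent(T_lat, cal$trust$thresholds)

  ## stable REC trait: support -> REC path a (observed-scale, compensated)
  a_lat <- st$k_rec * config$rf_paths$a
  rec_core <- a_lat * (sup_obs - st$rf_center[["support"]]) + stats::rnorm(N)
  theta_rec <- (rec_core - st$rec_center) / st$rec_scale

  ## presence per wave (dropout optionally distress-dependent, see below)
  present <- matrix(FALSE, N, 3)
  present[entry == 1, 1] <- TRUE

  ## reactivity / shared wave-noise setup
  kappa <- sqrt(config$reactivity_share)
  ds <- config$distress_share
  rho_eta <- if (kappa < 1) max(0, min(1, (ds - kappa^2) / (1 - kappa^2))) else 0

  phi <- config$exposure_autocorr
  lam <- cal$exposure$lambda
  n_items <- length(bank$items)

  E1c <- numeric(N)            # centred baseline exposure (0 for late entrants)
  rows <- vector("list", 3)
  distress_w <- rep(0, N)
  latents <- NULL

  for (w in 1:3) {
    if (w == 2) {
      keep <- present[, 1] & drop_keep(config, distress_w, config$retention[1])
      present[, 2] <- keep | (entry == 2)
    } else if (w == 3) {
      keep <- present[, 2] & drop_keep(config, distress_w, config$retention[2])
      present[, 3] <- keep | (entry == 3)
    }
    idx <- which(present[, w])
    n <- length(idx)
    if (!n) next

    X <- phi * Xp[idx] + sqrt(1 - phi^2) * stats::rnorm(n)
    adm <- administered_items(bank, w)
    k_adm <- length(adm)
    z <- lam * X + sqrt(1 - lam^2) * matrix(stats::rnorm(n * k_adm), n, k_adm)
    s_items <- matrix(NA_real_, n, n_items,
                      dimnames = list(NULL, bank$items))
    s_items[, adm] <- (z > cal$exposure$tau[w]) + 0
    E_true <- 100 * rowMeans(s_items[, adm, drop = FALSE])
    if (w == 1) E1c[idx] <- E_true - st$e_center

    ## wave-specific REC items (stable trait, fresh item noise)
    rec_items0 <- draw_item_block(theta_rec[idx], 6L, cal$rec$rho,
                                  cal$rec$thresholds) + 1L   # 1..5 recoded scale
    rec_obs <- rowMeans(rec_items0)
    rec_items <- rec_items0
    rec_items[, rec_reverse_flags] <- 6 - rec_items[, rec_reverse_flags]

    ## structural part shared between bases (standardised-SR units)
    rf <- config$rf_paths
    mo <- config$moderation
    pg <- st$path_gain %||% list(b = list(dep = 1, dis = 1),
                                 c = list(dep = 1, dis = 1),
                                 mod = list(dep = 1, dis = 1),
                                 cum = list(dep = 1, dis = 1))
    dsup <- sup_obs[idx] - st$rf_center[["support"]]
    dtr <- trust_obs[idx] - st$rf_center[["trust"]]
    drec <- rec_obs - st$rf_center[["rec"]]
    e1 <- E1c[idx]

    ## correlated residual components; right-skewed margins (symptom totals in
    ## low-burden populations are right-skewed, which a purely Gaussian latent
    ## cannot reproduce jointly with the probable-MDD tail share)
    dsk <- st$resid_skew %||% 0
    eta_c <- rskewnorm(n, dsk)
    eta_dep <- sqrt(rho_eta) * eta_c + sqrt(1 - rho_eta) * rskewnorm(n, dsk)
    eta_dis <- sqrt(rho_eta) * eta_c + sqrt(1 - rho_eta) * rskewnorm(n, dsk)
    V_dep <- kappa * R0[idx] + sqrt(1 - kappa^2) * eta_dep
    V_dis <- kappa * R0[idx] + sqrt(1 - kappa^2) * eta_dis

    dE <- E_true - st$e_center
    theta <- list()
    for (b in c("dep", "dis")) {
      sigma <- if (b == "dep") 5.4 else 6.1
      norm_part <- (st$beta1[[b]] * dE + st$beta2[[b]] * dE^2) / sigma
      mo_rec <- if (b == "dep") mo$rec_dep else mo$rec_dis
      S_b <- rf$c_prime / pg$c[[b]] * dsup + rf$trust * dtr +
        rf$b / pg$b[[b]] * drec +
        (mo$support * dsup + mo$trust * dtr + mo_rec * drec) * e1 / pg$mod[[b]] +
        config$cumulative_effect / pg$cum[[b]] * e1 * (w > 1)
      core <- norm_part + st$k2[[b]] * S_b +
        config$residual_noise_scale * (if (b == "dep") V_dep else V_dis)
      theta[[b]] <- (core - st$core_center[[b]]) / st$core_scale[[b]]
    }
    distress_w[idx] <- theta$dep
    if (keep_latents && w == 1L) {
      latents <- list(theta_dep = theta$dep, theta_dis = theta$dis,
                      theta_rec = theta_rec[idx])
    }

    phq_items <- draw_item_block(theta$dep, 9L, cal$phq9$rho, cal$phq9$thresholds)
    ghq_items <- draw_item_block(theta$dis, 12L, cal$ghq12$rho, cal$ghq12$thresholds)

    df <- data.frame(participant_id = id[idx], wave = w, age = age[idx],
                     gender = gender[idx], stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(s_items))
    colnames(phq_items) <- phq_cols
    colnames(ghq_items) <- ghq_cols
    colnames(rec_items) <- rec_cols
    df <- cbind(df, as.data.frame(phq_items), as.data.frame(ghq_items),
                as.data.frame(rec_items))
    df$support <- sup_obs[idx]
    df$trust <- trust_obs[idx]
    rows[[w]] <- apply_missingness(df, w, config, adm)
  }

  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  co <- cohort_table(out, bank)
  if (keep_latents) attr(co, "latents") <- latents
  co
}

## Bernoulli keep decisions; optional distress dependence via a logistic shift.
drop_keep <- function(config, distress, p_keep) {
  n <- length(distress)
  w <- config$dropout_distress_weight
  if (w == 0) return(stats::runif(n) < p_keep)
  lo <- stats::qlogis(p_keep) - w * distress
  stats::runif(n) < stats::plogis(lo)
}

apply_missingness <- function(df, w, config, adm) {
  mr <- config$missingness
  n <- nrow(df)
  blank <- function(cols, rate) {
    if (rate <= 0) return(invisible(NULL))
    hit <- stats::runif(n) < rate
    df[hit, cols] <<- NA
    invisible(NULL)
  }
  blank(adm, mr$stressors[w])
  blank(phq_cols, mr$phq9[w])
  blank(ghq_cols, mr$ghq12[w])
  blank(rec_cols, mr$rec[w])
  blank("support", mr$support[w])
  blank("trust", mr$trust[w])
  blank("age", mr$age[w])
  if (config$item_missing > 0) {
    m <- as.matrix(df[adm])
    cells <- matrix(stats::runif(n * length(adm)) < config$item_missing,
                    n, length(adm))
    m[cells] <- NA
    df[adm] <- m
  }
  df
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort generator: n_wave1 = %d, retention %.2f / %.3f, entrants %d / %d\n",
              x$n_wave1, x$retention[1], x$retention[2],
              x$new_entrants[1], x$new_entrants[2]))
  cat(sprintf("  exposure means %s%%, paths a=%.3g b=%.3g c'=%.3g trust=%.3g, cumulative %.3g\n",
              paste(x$exposure_mean, collapse = "/"),
              x$rf_paths$a, x$rf_paths$b, x$rf_paths$c_prime, x$rf_paths$trust,
              x$cumulative_effect))
  invisible(x)
}
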