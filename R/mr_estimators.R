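# Univariable causal-effect estimators on harmonized summary statistics:
# Wald ratio (single instrument, "cis-MR"), inverse-variance-weighted
# average of per-instrument ratios ("polygenic MR"), Cochran Q
# heterogeneity and the MR-Egger intercept pleiotropy test.

#' Convert a log-odds effect to OR with 95% CI
#'
#' @param beta log-odds causal effect.
#' @param se its standard error (> 0).
#' @return Named list `or_`, `ci_low`, `ci_high` with
#'   `or_ = exp(beta)` and CI bounds `exp(beta -/+ 1.96 * se)`.
#' @examples
#' effect_to_or_ci(-0.346, 0.135)  # OR 0.708 (0.544-0.921)
#' @export
effect_to_or_ci <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be positive")
  list(or_ = exp(beta),
       ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se))
}

two_sided_normal_p <- function(z) 2 * stats::pnorm(-abs(z))

mr_result <- function(exposure_id, outcome_id, method, level = NA_character_,
                      nsnp, beta, se,
                      Q = NA_real_, Q_df = NA_integer_, Q_pval = NA_real_,
                      egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                      p_pleio = NA_real_) {
  ci <- effect_to_or_ci(beta, se)
  structure(
    data.frame(exposure = exposure_id, outcome = outcome_id, method = method,
               level = level, nsnp = as.integer(nsnp),
               beta = beta, se = se,
               or_ = ci$or_, ci_low = ci$ci_low, ci_high = ci$ci_high,
               p_mr = two_sided_normal_p(beta / se),
               Q = Q, Q_df = Q_df, Q_pval = Q_pval,
               egger_intercept = egger_intercept,
               egger_intercept_se = egger_intercept_se,
               p_pleio = p_pleio,
               stringsAsFactors = FALSE),
    class = c("mr_result", "data.frame"))
}

#' Wald-ratio causal estimate from a single instrument
#'
#' `beta = b_gy / b_gx`; the default standard error is the first-order delta
#' approximation `se_gy / |b_gx|`. The second-order option adds the
#' contribution of the exposure-beta uncertainty,
#' `sqrt(se_gy^2 / b_gx^2 + b_gy^2 * se_gx^2 / b_gx^4)`.
#'
#' @param b_gx,se_gx instrument-exposure effect and SE (`b_gx` must be
#'   non-zero).
#' @param b_gy,se_gy instrument-outcome effect and SE.
#' @param exposure_id,outcome_id,level labels carried into the result.
#' @param second_order use the second-order delta-method SE.
#' @return A one-row `mr_result` data frame (method `"wald_ratio"`,
#'   `nsnp = 1`; heterogeneity and pleiotropy columns `NA`).
#' @export
wald_ratio <- function(b_gx, se_gx, b_gy, se_gy,
                       exposure_id = "exposure", outcome_id = "outcome",
                       level = NA_character_, second_order = FALSE) {
  if (!is.finite(b_gx) || b_gx == 0) {
    stop("Wald ratio undefined: instrument-exposure beta is zero")
  }
  beta <- b_gy / b_gx
  se <- if (second_order) {
    sqrt(se_gy^2 / b_gx^2 + b_gy^2 * se_gx^2 / b_gx^4)
  } else {
    se_gy / abs(b_gx)
  }
  mr_result(exposure_id, outcome_id, "wald_ratio", level, 1L, beta, se)
}

#' Inverse-variance-weighted causal estimate
#'
#' Pools per-instrument Wald ratios `beta_i = b_gy_i / b_gx_i` with weights
#' `w_i = 1 / se_i^2`, where `se_i = se_gy_i / |b_gx_i|` (first-order
#' ratio SE). The pooled estimate is `sum(w_i beta_i) / sum(w_i)` with
#' fixed-effect SE `sum(w_i)^(-1/2)`. Cochran's
#' `Q = sum(w_i (beta_i - beta)^2)` on `k - 1` degrees of freedom measures
#' instrument heterogeneity; in `multiplicative_random` mode (the default)
#' the SE is inflated by `max(1, sqrt(Q / (k - 1)))`, so it never drops
#' below the fixed-effect SE.
#'
#' @param instruments data frame of harmonized instruments with columns
#'   `beta_gx`, `se_gx`, `beta_gy`, `se_gy` (as from [harmonize_tables()]);
#'   at least two rows, all `beta_gx` non-zero.
#' @param mode `"multiplicative_random"` (default) or `"fixed"`.
#' @param exposure_id,outcome_id,level labels carried into the result.
#' @return A one-row `mr_result` data frame (method `"ivw"`) carrying `Q`,
#'   `Q_df` and the upper-tail chi-square `Q_pval`.
#' @export
ivw_estimate <- function(instruments, mode = c("multiplicative_random", "fixed"),
                         exposure_id = "exposure", outcome_id = "outcome",
                         level = NA_character_) {
  mode <- match.arg(mode)
  k <- nrow(instruments)
  if (k < 2L) {
    stop("IVW requires at least 2 instruments; use wald_ratio() for a single instrument")
  }
  if (any(instruments$beta_gx == 0)) stop("IVW undefined: an instrument-exposure beta is zero")
  ratio <- instruments$beta_gy / instruments$beta_gx
  ratio_se <- instruments$se_gy / abs(instruments$beta_gx)
  w <- 1 / ratio_se^2
  beta <- sum(w * ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  Q <- sum(w * (ratio - beta)^2)
  df <- k - 1L
  se <- if (mode == "fixed") se_fixed else se_fixed * max(1, sqrt(Q / df))
  mr_result(exposure_id, outcome_id, "ivw", level, k, beta, se,
            Q = Q, Q_df = df,
            Q_pval = stats::pchisq(Q, df = df, lower.tail = FALSE))
}

#' MR-Egger regression and intercept pleiotropy test
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an intercept, weights `1 / se_gy^2`, after orienting every
#' instrument so its exposure beta is non-negative (pair-wise sign flip;
#' required for the intercept to be interpretable as average directional
#' pleiotropy). The intercept p-value is a two-sided normal test.
#'
#' @inheritParams ivw_estimate
#' @return A list with `intercept`, `intercept_se`, `intercept_pval`,
#'   `slope`, `slope_se`, `slope_pval` and `nsnp`.
#' @export
egger_regression <- function(instruments) {
  k <- nrow(instruments)
  if (k < 3L) stop("MR-Egger requires at least 3 instruments")
  if (any(instruments$beta_gx == 0)) stop("MR-Egger undefined: an instrument-exposure beta is zero")
  flip <- sign(instruments$beta_gx)
  bx <- instruments$beta_gx * flip
  by <- instruments$beta_gy * flip
  w <- 1 / instruments$se_gy^2
  fit <- stats::lm(by ~ bx, weights = w)
  # lm's sigma absorbs over/under-dispersion; rescale to the analytic WLS
  # covariance (weights taken as known inverse variances), then allow
  # multiplicative over-dispersion with a floor at 1 as in IVW.
  sm <- summary(fit)
  coefs <- sm$coefficients
  phi <- max(1, sm$sigma)
  intercept <- coefs["(Intercept)", "Estimate"]
  intercept_se <- coefs["(Intercept)", "Std. Error"] / sm$sigma * phi
  slope <- coefs["bx", "Estimate"]
  slope_se <- coefs["bx", "Std. Error"] / sm$sigma * phi
  list(intercept = intercept,
       intercept_se = intercept_se,
       intercept_pval = two_sided_normal_p(intercept / intercept_se),
       slope = slope,
       slope_se = slope_se,
       slope_pval = two_sided_normal_p(slope / slope_se),
       nsnp = k)
}

#' Run univariable MR across screening levels
#'
#' For each screening level: screen the exposure table, clump to
#' LD-independent instruments, harmonize against the outcome, and dispatch
#' on the instrument count — Wald ratio at `k = 1`, IVW with Cochran Q at
#' `k >= 2`, plus the MR-Egger intercept at `k >= 3`. Diagnostics that a
#' given `k` cannot support are reported as `NA`.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param ld LD r-squared matrix covering the exposure's candidates.
#' @param levels character vector of level labels (default all four).
#' @param r2_threshold,window_bp clumping parameters (see [ld_clump()]).
#' @param mode IVW mode (see [ivw_estimate()]).
#' @param palindrome_eaf_window see [harmonize_pair()].
#' @return An `mr_result` data frame with one row per level that yielded at
#'   least one instrument; levels with none are skipped with a message.
#' @export
run_univariable_mr <- function(exposure, outcome, ld,
                               levels = names(SCREENING_LEVELS),
                               r2_threshold = 0.001, window_bp = 1e7,
                               mode = c("multiplicative_random", "fixed"),
                               palindrome_eaf_window = 0.08) {
  mode <- match.arg(mode)
  rows <- list()
  for (lev in levels) {
    iv <- select_instruments(exposure, lev, ld, r2_threshold, window_bp)
    if (nrow(iv) == 0L) {
      message(sprintf("run_univariable_mr: '%s' has no instruments at %s; level skipped",
                      exposure$trait_id, lev))
      next
    }
    sub <- exposure
    sub$variants <- iv
    h <- harmonize_tables(sub, outcome, palindrome_eaf_window)
    k <- nrow(h)
    if (k == 0L) {
      message(sprintf("run_univariable_mr: '%s' at %s lost all instruments in harmonization",
                      exposure$trait_id, lev))
      next
    }
    if (k == 1L) {
      res <- wald_ratio(h$beta_gx, h$se_gx, h$beta_gy, h$se_gy,
                        exposure$trait_id, outcome$trait_id, lev)
    } else {
      res <- ivw_estimate(h, mode, exposure$trait_id, outcome$trait_id, lev)
      if (k >= 3L) {
        eg <- egger_regression(h)
        res$egger_intercept <- eg$intercept
        res$egger_intercept_se <- eg$intercept_se
        res$p_pleio <- eg$intercept_pval
      }
    }
    rows[[lev]] <- res
  }
  if (!length(rows)) {
    return(mr_result("none", "none", "ivw", NA, 2L, 0, 1)[0, ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mr_result", "data.frame")
  out
}
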