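# Multivariable MR: joint weighted least squares of outcome effects on the
# matrix of exposure effects, giving each exposure's direct effect
# conditional on the others.

#' Assemble a multivariable MR design
#'
#' Builds the per-variant design from one harmonized table per exposure
#' (all against the same outcome): the instrument union across exposures,
#' with each exposure's beta looked up for every union variant (0 when the
#' variant is absent from that exposure's table).
#'
#' @param harmonized named list of data frames from [harmonize_tables()],
#'   one per exposure, names are the exposure ids.
#' @return A list with `exposure_ids`, `variant_id`, `X` (variants x
#'   exposures beta matrix), `beta_gy`, `se_gy`.
#' @export
mvmr_design <- function(harmonized) {
  stopifnot(is.list(harmonized), length(harmonized) >= 1L,
            !is.null(names(harmonized)))
  ids <- names(harmonized)
  union_variants <- unique(unlist(lapply(harmonized, `[[`, "variant_id")))
  X <- matrix(0, nrow = length(union_variants), ncol = length(ids),
              dimnames = list(union_variants, ids))
  beta_gy <- se_gy <- stats::setNames(rep(NA_real_, length(union_variants)),
                                      union_variants)
  for (id in ids) {
    h <- harmonized[[id]]
    X[h$variant_id, id] <- h$beta_gx
    beta_gy[h$variant_id] <- h$beta_gy
    se_gy[h$variant_id] <- h$se_gy
  }
  if (anyNA(beta_gy)) {
    stop("outcome effects missing for union variant(s): ",
         paste(union_variants[is.na(beta_gy)], collapse = ", "))
  }
  list(exposure_ids = ids, variant_id = union_variants,
       X = X, beta_gy = unname(beta_gy), se_gy = unname(se_gy))
}

#' Fit a multivariable MR model
#'
#' Weighted least squares of the outcome betas on the exposure-beta matrix,
#' no intercept, weights `1 / se_gy^2`. Per-coefficient p-values are
#' two-sided normal on the analytic WLS standard errors. An exposure is
#' `retained` when its p-value falls below `retain_p` (default 0.1).
#'
#' @param design a list as returned by [mvmr_design()].
#' @param retain_p retention threshold on the per-exposure p-value.
#' @return Data frame with one row per exposure: `exposure`, `beta`, `se`,
#'   `pval`, `or_`, `ci_low`, `ci_high`, `retained`.
#' @export
mvmr_fit <- function(design, retain_p = 0.1) {
  X <- design$X
  y <- design$beta_gy
  w <- 1 / design$se_gy^2
  m <- ncol(X)
  if (nrow(X) <= m) {
    stop("multivariable MR needs more instruments than exposures (",
         nrow(X), " variants for ", m, " exposures)")
  }
  Xw <- X * sqrt(w)
  qr_x <- qr(Xw)
  if (qr_x$rank < m) {
    bad <- design$exposure_ids[-qr_x$pivot[seq_len(qr_x$rank)]]
    stop("collinear exposure-beta columns in multivariable MR design: ",
         paste(bad, collapse = ", "))
  }
  XtWX <- crossprod(Xw)
  XtWy <- crossprod(X, w * y)
  beta <- drop(solve(XtWX, XtWy))
  se <- sqrt(diag(solve(XtWX)))
  pval <- two_sided_normal_p(beta / se)
  ci <- effect_to_or_ci(beta, se)
  data.frame(exposure = design$exposure_ids,
             beta = beta, se = se, pval = pval,
             or_ = ci$or_, ci_low = ci$ci_low, ci_high = ci$ci_high,
             retained = pval < retain_p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Adjusted effect of one exposure from a joint model
#'
#' Fits the multivariable model containing the primary exposure plus the
#' given adjustment exposures, and returns the primary exposure's direct
#' effect with OR/CI, mirroring an "adjusted by X" analysis.
#'
#' @param primary_exposure id of the exposure of interest.
#' @param adjust_for character vector of exposure ids to condition on.
#' @param harmonized named list of harmonized tables (see [mvmr_design()])
#'   containing at least the primary and adjustment exposures.
#' @return One-row data frame as in [mvmr_fit()], for the primary exposure
#'   only, with an `adjusted_by` column.
#' @export
mvmr_adjusted_effect <- function(primary_exposure, adjust_for, harmonized) {
  if (primary_exposure %in% adjust_for) {
    stop("collinear design: cannot adjust '", primary_exposure, "' for itself")
  }
  ids <- c(primary_exposure, adjust_for)
  missing_ids <- setdiff(ids, names(harmonized))
  if (length(missing_ids)) {
    stop("no harmonized data for exposure(s): ", paste(missing_ids, collapse = ", "))
  }
  fit <- mvmr_fit(mvmr_design(harmonized[ids]))
  out <- fit[fit$exposure == primary_exposure, , drop = FALSE]
  out$adjusted_by <- paste(adjust_for, collapse = ",")
  rownames(out) <- NULL
  out
}
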