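# Approximate-Bayes-factor colocalization under the single-causal-variant
# assumption: per-variant Wakefield log-ABFs for two traits over a shared
# region, combined into posterior probabilities for the five hypotheses
#   H0 no association; H1/H2 one trait only; H3 two distinct causal
#   variants; H4 one shared causal variant.

#' Wakefield approximate log Bayes factor
#'
#' For an estimated effect `beta` with standard error `se` and a normal
#' effect-size prior with standard deviation `prior_sd`, the approximate
#' Bayes factor against the null is
#' `log ABF = 0.5 * log(V / (V + W)) + z^2 * W / (2 * (V + W))`
#' with `V = se^2`, `W = prior_sd^2`, `z = beta / se`. It is monotonically
#' increasing in `|z|` at fixed V and W.
#'
#' @param beta,se effect estimate and standard error (`se > 0`), vectorized.
#' @param prior_sd prior standard deviation of the true effect
#'   (default 0.2; use about 0.15 for binary-trait log-odds).
#' @return log approximate Bayes factor (natural log), same length as
#'   `beta`.
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.2) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be positive")
  if (!is.finite(prior_sd) || prior_sd <= 0) stop("prior_sd must be positive")
  V <- se^2
  W <- prior_sd^2
  z <- beta / se
  0.5 * log(V / (V + W)) + z^2 * W / (2 * (V + W))
}

log_sum_exp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, guarded against cancellation.
log_diff_exp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Build a two-trait region pair
#'
#' Aligns two per-variant effect tables over their shared ordered variant
#' list for colocalization.
#'
#' @param variant_id shared variant ids, in region order.
#' @param beta1,se1 trait-1 effects and SEs.
#' @param beta2,se2 trait-2 effects and SEs.
#' @param trait_types length-2 character, `"quantitative"` or `"binary"`,
#'   used to pick default prior SDs.
#' @return A list of class `region_pair`.
#' @export
region_pair <- function(variant_id, beta1, se1, beta2, se2,
                        trait_types = c("quantitative", "quantitative")) {
  n <- length(variant_id)
  if (length(beta1) != n || length(se1) != n ||
      length(beta2) != n || length(se2) != n) {
    stop("misaligned region: all per-variant vectors must match variant_id in length")
  }
  if (anyDuplicated(variant_id)) stop("duplicate variant ids in region")
  trait_types <- match.arg(trait_types, c("quantitative", "binary"),
                           several.ok = TRUE)
  structure(list(variant_id = as.character(variant_id),
                 beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                 trait_types = rep(trait_types, length.out = 2L)),
            class = "region_pair")
}

default_prior_sd <- function(trait_type) {
  if (trait_type == "binary") 0.15 else 0.2
}

#' Colocalization posterior probabilities
#'
#' Computes per-variant Wakefield log-ABFs for both traits and combines
#' them, under the single-causal-variant-per-trait assumption, into the
#' posterior probabilities of the five hypotheses. With per-variant Bayes
#' factors BF1, BF2 the unnormalized hypothesis weights are
#' H0: 1; H1: `p1 * sum(BF1)`; H2: `p2 * sum(BF2)`;
#' H3: `p1 * p2 * (sum(BF1) * sum(BF2) - sum(BF1 * BF2))`;
#' H4: `p12 * sum(BF1 * BF2)`. All accumulation is in log space.
#'
#' @param region a [region_pair()].
#' @param p1,p2 prior probability a variant is causal for trait 1 / trait 2
#'   only (defaults 1e-4).
#' @param p12 prior probability a variant is causal for both (default 1e-5).
#' @param prior_sd1,prior_sd2 effect-size prior SDs; defaults depend on the
#'   region's trait types (0.2 quantitative, 0.15 binary log-odds).
#' @return A list of class `coloc_result`: `pp` (named PP.H0..PP.H4, sums
#'   to 1), `priors`, `n_variants` and `labf` (per-variant log-ABF table).
#' @export
coloc_posteriors <- function(region, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             prior_sd1 = NULL, prior_sd2 = NULL) {
  stopifnot(inherits(region, "region_pair"))
  Q <- length(region$variant_id)
  if (Q < 2L) stop("colocalization requires at least 2 shared variants")
  if (is.null(prior_sd1)) prior_sd1 <- default_prior_sd(region$trait_types[1L])
  if (is.null(prior_sd2)) prior_sd2 <- default_prior_sd(region$trait_types[2L])
  l1 <- wakefield_abf(region$beta1, region$se1, prior_sd1)
  l2 <- wakefield_abf(region$beta2, region$se2, prior_sd2)

  ls1 <- log_sum_exp(l1)                 # log sum BF1
  ls2 <- log_sum_exp(l2)                 # log sum BF2
  ls12 <- log_sum_exp(l1 + l2)           # log sum BF1*BF2 (same variant)
  lh <- c(H0 = 0,
          H1 = log(p1) + ls1,
          H2 = log(p2) + ls2,
          H3 = log(p1) + log(p2) + log_diff_exp(ls1 + ls2, ls12),
          H4 = log(p12) + ls12)
  pp <- exp(lh - log_sum_exp(lh))
  names(pp) <- paste0("PP.", names(lh))
  structure(list(pp = pp,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 prior_sd = c(prior_sd1, prior_sd2),
                 n_variants = Q,
                 labf = data.frame(variant_id = region$variant_id,
                                   labf1 = l1, labf2 = l2,
                                   stringsAsFactors = FALSE)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d variants; priors p1=%g p2=%g p12=%g\n",
              x$n_variants, x$priors["p1"], x$priors["p2"], x$priors["p12"]))
  print(round(x$pp, 4))
  invisible(x)
}

#' Extract a region around a lead variant
#'
#' Returns the variants on the lead variant's chromosome within
#' `window_bp` of its position (closed interval, so variants exactly at the
#' boundary are included), sorted by position.
#'
#' @param table a [sumstats] object.
#' @param lead_variant_id id of the lead variant (must be present).
#' @param window_bp flank size in base pairs on each side (default 50,000).
#' @return Data frame slice of the table's variants.
#' @export
extract_region <- function(table, lead_variant_id, window_bp = 50000L) {
  stopifnot(inherits(table, "sumstats"))
  v <- table$variants
  i <- match(lead_variant_id, v$variant_id)
  if (is.na(i)) stop("lead variant '", lead_variant_id, "' not found in table")
  lead <- v[i, ]
  slice <- v[v$chrom == lead$chrom & abs(v$pos - lead$pos) <= window_bp, ,
             drop = FALSE]
  slice <- slice[order(slice$pos), , drop = FALSE]
  rownames(slice) <- NULL
  slice
}

#' Colocalize two traits around a lead variant
#'
#' Extracts the +/- `window_bp` region from both tables, intersects the
#' variant lists, and runs [coloc_posteriors()].
#'
#' @param table1,table2 [sumstats] objects.
#' @inheritParams extract_region
#' @inheritParams coloc_posteriors
#' @return A `coloc_result`.
#' @export
coloc_region <- function(table1, table2, lead_variant_id, window_bp = 50000L,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  r1 <- extract_region(table1, lead_variant_id, window_bp)
  r2 <- extract_region(table2, lead_variant_id, window_bp)
  shared <- intersect(r1$variant_id, r2$variant_id)
  if (length(shared) < 2L) stop("fewer than 2 shared variants in region")
  i1 <- match(shared, r1$variant_id)
  i2 <- match(shared, r2$variant_id)
  region <- region_pair(shared,
                        r1$beta[i1], r1$se[i1],
                        r2$beta[i2], r2$se[i2],
                        trait_types = c(table1$trait_type, table2$trait_type))
  coloc_posteriors(region, p1 = p1, p2 = p2, p12 = p12)
}
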