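# Synthetic two-sample GWAS summary statistics with known causal
# architecture. Summary statistics are simulated directly (no
# individual-level genotypes): estimated betas are drawn around their true
# marginal values with the sampling SE implied by sample size and allele
# frequency, and with LD-correlated noise within blocks.
#
# SE formulas (standardized phenotype / log-odds outcome):
#   quantitative: se = 1 / sqrt(2 f (1-f) n)
#   binary:       se = 1 / sqrt(2 f (1-f) n cf (1-cf))
# where f is the effect-allele frequency and cf the case fraction.

NONPALINDROMIC_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                                 "G", "A", "G", "T", "T", "C", "T", "G"),
                               ncol = 2L, byrow = TRUE)

se_quantitative <- function(eaf, n) 1 / sqrt(2 * eaf * (1 - eaf) * n)

se_binary <- function(eaf, n, case_fraction) {
  1 / sqrt(2 * eaf * (1 - eaf) * n * case_fraction * (1 - case_fraction))
}

#' Simulation configuration
#'
#' Parameters of the synthetic GWAS architecture. Defaults mimic the shape
#' of a microbiome-exposure / severe-disease-outcome design at desk scale:
#' 20 exposure traits with 2-26 LD-independent instruments each, exposure
#' GWAS of 18,473 samples, one binary outcome on the log-odds scale.
#'
#' @param n_exposures number of exposure traits.
#' @param n_causal how many exposures have a true causal effect on the
#'   outcome (the first `n_causal` of them).
#' @param theta causal-effect magnitude for causal exposures (signs
#'   alternate), or a vector of per-exposure effects (length
#'   `n_exposures`, overriding `n_causal`).
#' @param k_instruments instruments per exposure: a single count, or a
#'   range `c(min, max)` sampled per exposure.
#' @param inst_effect_range range of absolute per-allele instrument effect
#'   sizes on the exposure.
#' @param eaf_range effect-allele frequency range.
#' @param n_exposure_samples,n_outcome_samples GWAS sample sizes.
#' @param case_fraction outcome case fraction in (0,1).
#' @param pleiotropy `"none"`, `"balanced"` (instrument-level direct
#'   effects ~ N(0, magnitude)) or `"directional"` (constant direct effect
#'   = magnitude).
#' @param pleiotropy_magnitude pleiotropy magnitude on the outcome
#'   log-odds scale.
#' @param block_size variants per LD block (the causal instrument plus
#'   `block_size - 1` correlated neighbours); 1 disables LD.
#' @param ld_rho AR(1) correlation between adjacent variants in a block,
#'   in [0, 1).
#' @param n_null_blocks extra blocks per exposure with no causal variant.
#' @param seed RNG seed; every generated dataset is reproducible from
#'   (config, seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_exposures = 20L, n_causal = min(5L, n_exposures),
                       theta = 0.5,
                       k_instruments = c(2L, 26L),
                       inst_effect_range = c(0.08, 0.25),
                       eaf_range = c(0.1, 0.9),
                       n_exposure_samples = 18473L,
                       n_outcome_samples = 50000L,
                       case_fraction = 0.1,
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_magnitude = 0.1,
                       block_size = 5L, ld_rho = 0.8,
                       n_null_blocks = 2L, seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  cfg <- list(n_exposures = as.integer(n_exposures),
              n_causal = as.integer(n_causal),
              theta = theta,
              k_instruments = as.integer(k_instruments),
              inst_effect_range = inst_effect_range,
              eaf_range = eaf_range,
              n_exposure_samples = as.integer(n_exposure_samples),
              n_outcome_samples = as.integer(n_outcome_samples),
              case_fraction = case_fraction,
              pleiotropy = pleiotropy,
              pleiotropy_magnitude = pleiotropy_magnitude,
              block_size = as.integer(block_size),
              ld_rho = ld_rho,
              n_null_blocks = as.integer(n_null_blocks),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_exposures < 1L) stop("n_exposures must be positive")
  if (cfg$n_causal < 0L || cfg$n_causal > cfg$n_exposures)
    stop("n_causal must be between 0 and n_exposures")
  if (any(cfg$k_instruments < 1L)) stop("instrument counts must be positive")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (cfg$case_fraction <= 0 || cfg$case_fraction >= 1)
    stop("case_fraction must lie in (0, 1)")
  if (cfg$block_size < 1L) stop("block_size must be positive")
  if (any(cfg$eaf_range <= 0) || any(cfg$eaf_range >= 1))
    stop("eaf_range must lie inside (0, 1)")
  invisible(cfg)
}

ar1_correlation <- function(p, rho) rho ^ abs(outer(seq_len(p), seq_len(p), "-"))

# Draw estimated betas around truth with LD-correlated sampling noise.
draw_betas <- function(truth, se, corr) {
  if (length(truth) == 1L) return(stats::rnorm(1L, truth, se))
  sigma <- outer(se, se) * corr
  drop(MASS::mvrnorm(1L, mu = truth, Sigma = sigma))
}

#' Simulate exposure and outcome summary statistics
#'
#' Generates one summary-statistics table per exposure trait plus a shared
#' binary-outcome table, a block-diagonal LD r-squared matrix and the truth
#' set. Each exposure lives on its own chromosome; each instrument sits in
#' its own AR(1) LD block whose neighbours carry the LD-propagated marginal
#' effect; per-exposure null blocks carry no signal. The outcome effect of
#' every variant is `theta * (true exposure effect)` plus any planted
#' pleiotropy, observed at the outcome GWAS's standard errors. Outcome rows
#' have their allele coding randomly swapped relative to the exposure rows
#' so harmonization is exercised.
#'
#' @param config a [sim_config()].
#' @return A list with `exposures` (named list of [sumstats]), `outcome`
#'   (a [sumstats]), `ld` (r-squared matrix over all variants) and `truth`
#'   (per-exposure theta and instrument table, plus the config).
#' @export
simulate_exposure_outcome <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  theta <- config$theta
  if (length(theta) == 1L) {
    theta <- rep(0, config$n_exposures)
    if (config$n_causal > 0L) {
      idx <- seq_len(config$n_causal)
      theta[idx] <- config$theta[1L] * (-1) ^ (idx + 1)
    }
  }
  stopifnot(length(theta) == config$n_exposures)

  exposures <- vector("list", config$n_exposures)
  names(exposures) <- sprintf("exposure_%02d", seq_len(config$n_exposures))
  outcome_rows <- list()
  ld_blocks <- list()
  truth_instruments <- list()

  for (e in seq_len(config$n_exposures)) {
    k <- if (length(config$k_instruments) == 1L) config$k_instruments else
      sample(seq(config$k_instruments[1L], config$k_instruments[2L]), 1L)
    n_blocks <- k + config$n_null_blocks
    bs <- config$block_size
    p <- n_blocks * bs
    gamma <- stats::runif(k, config$inst_effect_range[1L], config$inst_effect_range[2L]) *
      sample(c(-1, 1), k, replace = TRUE)
    eaf <- stats::runif(p, config$eaf_range[1L], config$eaf_range[2L])
    se_x <- se_quantitative(eaf, config$n_exposure_samples)
    se_y <- se_binary(eaf, config$n_outcome_samples, config$case_fraction)
    alleles <- NONPALINDROMIC_PAIRS[sample(nrow(NONPALINDROMIC_PAIRS), p, replace = TRUE), ,
                                    drop = FALSE]
    causal_in_block <- (bs + 1L) %/% 2L   # causal variant mid-block
    corr <- ar1_correlation(bs, config$ld_rho)

    # directional pleiotropy is defined relative to the exposure-increasing
    # allele (as the Egger intercept is, after pair orientation)
    alpha <- switch(config$pleiotropy,
                    none = rep(0, k),
                    balanced = stats::rnorm(k, 0, config$pleiotropy_magnitude),
                    directional = config$pleiotropy_magnitude * sign(gamma))

    true_x <- true_y <- numeric(p)
    beta_x <- beta_y <- numeric(p)
    for (b in seq_len(n_blocks)) {
      idx <- ((b - 1L) * bs + 1L):(b * bs)
      if (b <= k) {
        r_to_causal <- corr[causal_in_block, ]
        tx <- gamma[b] * r_to_causal
        ty <- theta[e] * tx + alpha[b] * r_to_causal
      } else {
        tx <- ty <- numeric(bs)
      }
      true_x[idx] <- tx
      true_y[idx] <- ty
      beta_x[idx] <- draw_betas(tx, se_x[idx], corr)
      beta_y[idx] <- draw_betas(ty, se_y[idx], corr)
    }

    chrom <- as.character(e)
    pos <- as.integer(rep((seq_len(n_blocks) - 1L) * 1e6, each = bs) +
                        seq_len(bs) * 1000L)
    ids <- sprintf("rs%d_%04d", e, seq_len(p))
    vx <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                     effect_allele = alleles[, 1L], other_allele = alleles[, 2L],
                     eaf = eaf, beta = beta_x, se = se_x,
                     pval = 2 * stats::pnorm(-abs(beta_x / se_x)),
                     n = config$n_exposure_samples, stringsAsFactors = FALSE)
    exposures[[e]] <- sumstats(vx, names(exposures)[e], "quantitative",
                               validate = FALSE)

    # outcome rows: random allele swap exercises harmonization downstream
    swap <- stats::runif(p) < 0.3
    vy <- vx
    vy$beta <- ifelse(swap, -beta_y, beta_y)
    vy$se <- se_y
    vy$pval <- 2 * stats::pnorm(-abs(beta_y / se_y))
    vy$eaf <- ifelse(swap, 1 - eaf, eaf)
    vy$effect_allele <- ifelse(swap, alleles[, 2L], alleles[, 1L])
    vy$other_allele <- ifelse(swap, alleles[, 1L], alleles[, 2L])
    vy$n <- config$n_outcome_samples
    outcome_rows[[e]] <- vy

    ld_blocks[[e]] <- Matrix::bdiag(replicate(n_blocks, corr ^ 2,
                                              simplify = FALSE))
    truth_instruments[[e]] <- data.frame(
      exposure = names(exposures)[e],
      variant_id = ids[(seq_len(k) - 1L) * bs + causal_in_block],
      gamma = gamma, alpha = alpha, stringsAsFactors = FALSE)
  }

  outcome_df <- do.call(rbind, outcome_rows)
  outcome <- sumstats(outcome_df, "outcome", "binary",
                      case_fraction = config$case_fraction, validate = FALSE)
  ld <- as.matrix(Matrix::bdiag(ld_blocks))
  all_ids <- unlist(lapply(exposures, function(s) s$variants$variant_id),
                    use.names = FALSE)
  dimnames(ld) <- list(all_ids, all_ids)

  list(exposures = exposures, outcome = outcome, ld = ld,
       truth = list(theta = stats::setNames(theta, names(exposures)),
                    instruments = do.call(rbind, truth_instruments),
                    config = config, seed = config$seed))
}

#' Simulate a planted mediation triangle
#'
#' Three traits: exposure E (quantitative), mediator M (quantitative) and
#' binary outcome O. E's instruments affect M through `theta_EM` and O both
#' through M (`theta_EM * theta_MO`) and directly (`theta_dir`); M's own
#' instruments affect only M and, through `theta_MO`, O. The implied true
#' proportion mediated is
#' `theta_EM * theta_MO / (theta_EM * theta_MO + theta_dir)`.
#'
#' Default effect sizes and sample sizes are chosen so that E's instruments
#' are strong for E but remain below genome-wide-suggestive significance in
#' M's GWAS — as for the weak microbial effects on metabolites they mimic —
#' so the mediator's screened instrument set stays distinct from the
#' exposure's.
#'
#' @param theta_EM,theta_MO,theta_dir true path coefficients (exposure on
#'   mediator, mediator on outcome, direct exposure on outcome).
#' @param k_E,k_M instruments for E and M.
#' @param n_E,n_M,n_O GWAS sample sizes.
#' @param case_fraction outcome case fraction.
#' @param inst_effect_range,eaf_range as in [sim_config()].
#' @param seed RNG seed.
#' @return A list with `tables` (named list of [sumstats]: E, M, O), `ld`
#'   (identity r-squared matrix: instruments independent) and `truth`
#'   (path coefficients and implied proportion mediated).
#' @export
simulate_mediation_triangle <- function(theta_EM = 0.25, theta_MO = 0.4,
                                        theta_dir = theta_EM * theta_MO * 7 / 3,
                                        k_E = 10L, k_M = 8L,
                                        n_E = 18473L, n_M = 7824L, n_O = 50000L,
                                        case_fraction = 0.1,
                                        inst_effect_range = c(0.105, 0.135),
                                        eaf_range = c(0.25, 0.35),
                                        seed = 1L) {
  set.seed(seed)
  p <- k_E + k_M
  gamma_E <- stats::runif(k_E, inst_effect_range[1L], inst_effect_range[2L]) *
    sample(c(-1, 1), k_E, replace = TRUE)
  gamma_M <- stats::runif(k_M, inst_effect_range[1L], inst_effect_range[2L]) *
    sample(c(-1, 1), k_M, replace = TRUE)
  eaf <- stats::runif(p, eaf_range[1L], eaf_range[2L])
  is_E <- seq_len(p) <= k_E

  true_on_E <- c(gamma_E, rep(0, k_M))
  true_on_M <- c(theta_EM * gamma_E, gamma_M)
  total_EO <- theta_EM * theta_MO + theta_dir
  true_on_O <- c(total_EO * gamma_E, theta_MO * gamma_M)

  se_E <- se_quantitative(eaf, n_E)
  se_M <- se_quantitative(eaf, n_M)
  se_O <- se_binary(eaf, n_O, case_fraction)

  alleles <- NONPALINDROMIC_PAIRS[sample(nrow(NONPALINDROMIC_PAIRS), p, replace = TRUE), ,
                                  drop = FALSE]
  ids <- sprintf("rs%s_%03d", ifelse(is_E, "E", "M"),
                 c(seq_len(k_E), seq_len(k_M)))
  chrom <- ifelse(is_E, "1", "2")
  pos <- as.integer(c(seq_len(k_E), seq_len(k_M)) * 1e6)

  make_table <- function(truth, se, trait_id, trait_type, n,
                         case_fraction = NA_real_) {
    beta <- stats::rnorm(p, truth, se)
    sumstats(data.frame(variant_id = ids, chrom = chrom, pos = pos,
                        effect_allele = alleles[, 1L], other_allele = alleles[, 2L],
                        eaf = eaf, beta = beta, se = se,
                        pval = 2 * stats::pnorm(-abs(beta / se)),
                        n = n, stringsAsFactors = FALSE),
             trait_id, trait_type, case_fraction = case_fraction,
             validate = FALSE)
  }
  tables <- list(
    E = make_table(true_on_E, se_E, "E", "quantitative", n_E),
    M = make_table(true_on_M, se_M, "M", "quantitative", n_M),
    O = make_table(true_on_O, se_O, "O", "binary", n_O, case_fraction))

  ld <- diag(p)
  dimnames(ld) <- list(ids, ids)

  list(tables = tables, ld = ld,
       truth = list(theta_EM = theta_EM, theta_MO = theta_MO,
                    theta_dir = theta_dir, theta_EO = total_EO,
                    proportion_mediated = theta_EM * theta_MO / total_EO,
                    gamma_E = gamma_E, gamma_M = gamma_M, seed = seed))
}

#' Simulate a two-trait colocalization region
#'
#' One AR(1)-correlated region observed in two GWAS. Each trait has one
#' causal variant (the same variant iff `shared`); marginal effects
#' propagate through the LD correlation and estimated betas are drawn with
#' LD-correlated noise at the sample-size-implied SEs.
#'
#' @param shared do the two traits share their causal variant?
#' @param n_variants variants in the region (default 200).
#' @param rho AR(1) LD correlation (default 0.9).
#' @param n1,n2 GWAS sample sizes (default 50,000 each).
#' @param b_causal causal-variant effect size for both traits.
#' @param causal_index index of trait 1's causal variant; trait 2 uses the
#'   same when `shared`, else a variant `n_variants/2` positions away.
#' @param eaf effect-allele frequency (single value for the region).
#' @param spacing_bp distance between adjacent variants.
#' @param seed RNG seed.
#' @return A list with `region` (a [region_pair()]), `tables` (two
#'   [sumstats] with coordinates, for [coloc_region()]), and `truth`.
#' @export
simulate_coloc_region <- function(shared = TRUE, n_variants = 200L, rho = 0.9,
                                  n1 = 50000L, n2 = 50000L, b_causal = 0.08,
                                  causal_index = n_variants %/% 4L,
                                  eaf = 0.3, spacing_bp = 500L, seed = 1L) {
  set.seed(seed)
  p <- as.integer(n_variants)
  c1 <- as.integer(causal_index)
  c2 <- if (shared) c1 else c1 + p %/% 2L
  stopifnot(c1 >= 1L, c2 <= p)
  corr <- ar1_correlation(p, rho)
  se1 <- rep(se_quantitative(eaf, n1), p)
  se2 <- rep(se_quantitative(eaf, n2), p)
  truth1 <- if (is.null(b_causal) || b_causal == 0) numeric(p) else
    b_causal * corr[c1, ]
  truth2 <- if (is.null(b_causal) || b_causal == 0) numeric(p) else
    b_causal * corr[c2, ]
  beta1 <- draw_betas(truth1, se1, corr)
  beta2 <- draw_betas(truth2, se2, corr)

  ids <- sprintf("rsR_%03d", seq_len(p))
  pos <- as.integer(seq_len(p)) * as.integer(spacing_bp)
  region <- region_pair(ids, beta1, se1, beta2, se2,
                        trait_types = c("quantitative", "quantitative"))
  make <- function(beta, se, n, trait_id) {
    sumstats(data.frame(variant_id = ids, chrom = "1", pos = pos,
                        effect_allele = "A", other_allele = "G",
                        eaf = eaf, beta = beta, se = se,
                        pval = 2 * stats::pnorm(-abs(beta / se)),
                        n = n, stringsAsFactors = FALSE),
             trait_id, "quantitative", validate = FALSE)
  }
  list(region = region,
       tables = list(trait1 = make(beta1, se1, n1, "trait1"),
                     trait2 = make(beta2, se2, n2, "trait2")),
       truth = list(shared = shared, causal1 = ids[c1], causal2 = ids[c2],
                    b_causal = b_causal, seed = seed))
}
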