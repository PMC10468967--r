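# Small in-code fixtures shared across tests.

make_variants <- function(n = 3L, chrom = "1", pos = seq_len(n) * 1000L,
                          beta = rep(0.1, n), se = rep(0.02, n),
                          pval = rep(1e-6, n), eaf = rep(0.3, n),
                          effect_allele = rep("A", n),
                          other_allele = rep("G", n)) {
  data.frame(variant_id = sprintf("rs%d", seq_len(n)),
             chrom = rep(chrom, length.out = n),
             pos = pos, effect_allele = rep(effect_allele, length.out = n),
             other_allele = rep(other_allele, length.out = n),
             eaf = eaf, beta = beta, se = se,
             pval = pval, n = rep(1000L, n), stringsAsFactors = FALSE)
}

make_table <- function(..., trait_id = "trait", trait_type = "quantitative") {
  sumstats(make_variants(...), trait_id, trait_type)
}

# instruments data frame in the harmonized layout used by the estimators
make_instruments <- function(beta_gx, se_gx, beta_gy, se_gy) {
  data.frame(variant_id = sprintf("rs%d", seq_along(beta_gx)),
             beta_gx = beta_gx, se_gx = se_gx,
             beta_gy = beta_gy, se_gy = se_gy, stringsAsFactors = FALSE)
}

one_variant_row <- function(variant_id = "rs1", effect_allele = "A",
                            other_allele = "G", beta = 0.2, eaf = 0.3,
                            se = 0.05, pval = 1e-6) {
  data.frame(variant_id = variant_id, chrom = "1", pos = 1000L,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = 1000L,
             stringsAsFactors = FALSE)
}
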