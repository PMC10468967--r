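# Reading, writing, validation and allele harmonization.

test_that("well-formed tables round-trip through read/write identically", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- make_table(n = 3L, beta = c(0.1, -0.2, 0.05), pval = c(1e-6, 1e-8, 0.3))
  write_sumstats(tab, path)
  back <- read_sumstats(path, trait_id = "trait")
  expect_equal(back$variants, tab$variants)

  # 100-record synthetic table, field-by-field
  set.seed(42)
  big <- make_table(n = 100L, beta = rnorm(100), se = runif(100, 0.01, 0.1),
                    pval = runif(100), eaf = runif(100))
  write_sumstats(big, path)
  expect_equal(read_sumstats(path)$variants, big$variants)

  # missing eaf survives as NA
  v <- make_variants(2L); v$eaf <- NA_real_
  na_tab <- sumstats(v, "t")
  write_sumstats(na_tab, path)
  expect_true(all(is.na(read_sumstats(path)$variants$eaf)))
})

test_that("empty table writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(make_table(n = 0L), path)
  expect_identical(length(readLines(path)), 1L)
  expect_identical(nrow(read_sumstats(path)$variants), 0L)
})

test_that("invalid rows are rejected and counted, valid rows kept in order", {
  v <- make_variants(4L)
  v$se[2] <- 0                     # non-positive SE
  v$pval[4] <- 0                   # p outside (0,1]
  expect_message(tab <- sumstats(v, "t"), "rejected 2 row")
  expect_identical(attr(tab, "n_rejected"), 2L)
  expect_identical(tab$variants$variant_id, c("rs1", "rs3"))
})

test_that("header aliases map to the same parse as canonical headers", {
  canon <- withr::local_tempfile(fileext = ".tsv")
  alias <- withr::local_tempfile(fileext = ".tsv")
  tab <- make_table(n = 5L, beta = seq(0.1, 0.5, by = 0.1))
  write_sumstats(tab, canon)
  txt <- readLines(canon)
  txt[1] <- "SNP\tCHR\tBP\tEA\tOA\tEAF\tBETA\tSE\tP\tN"
  writeLines(txt, alias)
  mapped <- read_sumstats(alias, trait_id = "trait",
                          column_map = c(SNP = "variant_id", CHR = "chrom",
                                         BP = "pos", EA = "effect_allele",
                                         OA = "other_allele", EAF = "eaf",
                                         BETA = "beta", SE = "se",
                                         P = "pval", N = "n"))
  expect_equal(mapped$variants, read_sumstats(canon, trait_id = "trait")$variants)
})

test_that("missing mandatory columns raise a format error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tbeta", "rs1\t0.1"), path)
  expect_error(read_sumstats(path), "mandatory column")
})

test_that("allele swap flips the outcome beta and EAF", {
  h <- harmonize_pair(one_variant_row(effect_allele = "A", other_allele = "G",
                                      beta = 0.2),
                      one_variant_row(effect_allele = "G", other_allele = "A",
                                      beta = 0.3, eaf = 0.7))
  expect_identical(h$action, "keep")
  expect_equal(h$outcome$beta, -0.3)
  expect_equal(h$outcome$eaf, 0.3)
  expect_identical(h$outcome$effect_allele, "A")
  expect_identical(h$outcome$other_allele, "G")
})

test_that("palindromic variants near EAF 0.5 or with missing EAF are dropped", {
  pal <- function(eaf_x, eaf_y) {
    harmonize_pair(one_variant_row(effect_allele = "A", other_allele = "T",
                                   eaf = eaf_x),
                   one_variant_row(effect_allele = "A", other_allele = "T",
                                   eaf = eaf_y))
  }
  expect_identical(pal(0.50, 0.3)$action, "drop")
  expect_identical(pal(0.55, 0.3)$action, "drop")  # inside default window 0.08
  expect_identical(pal(NA, 0.3)$action, "drop")
  # outside the window: oriented by EAF side
  same <- pal(0.2, 0.25)
  expect_identical(same$action, "keep")
  expect_equal(same$outcome$beta, 0.2)
  opp <- pal(0.2, 0.8)
  expect_identical(opp$action, "keep")
  expect_equal(opp$outcome$beta, -0.2)
  expect_equal(opp$outcome$eaf, 0.2)
})

test_that("all 12 non-palindromic allele configurations match the truth table", {
  # exposure fixed at A/G; outcome runs over every ordered pair of distinct
  # alleles. Expected verdicts built by hand:
  #   A/G same; G/A swap; T/C strand-flip same; C/T strand-flip swap;
  #   everything else irreconcilable.
  truth <- list(
    c("A", "G", "keep",  1),  c("G", "A", "keep", -1),
    c("T", "C", "keep",  1),  c("C", "T", "keep", -1),
    c("A", "C", "drop", NA),  c("C", "A", "drop", NA),
    c("A", "T", "drop", NA),  c("T", "A", "drop", NA),
    c("C", "G", "drop", NA),  c("G", "C", "drop", NA),
    c("G", "T", "drop", NA),  c("T", "G", "drop", NA))
  for (case in truth) {
    h <- harmonize_pair(one_variant_row(effect_allele = "A", other_allele = "G",
                                        beta = 0.2),
                        one_variant_row(effect_allele = case[1],
                                        other_allele = case[2], beta = 0.3))
    expect_identical(h$action, case[3],
                     info = paste("outcome alleles", case[1], case[2]))
    if (case[3] == "keep") {
      expect_equal(h$outcome$beta, 0.3 * as.numeric(case[4]),
                   info = paste("sign for", case[1], case[2]))
      expect_identical(h$outcome$effect_allele, "A")
    }
  }
})

test_that("harmonization is an involution and aligns effect alleles", {
  set.seed(11)
  pairs <- NULL
  for (i in 1:50) {
    ex <- one_variant_row(beta = rnorm(1), eaf = runif(1, 0.05, 0.45))
    alleles <- list(c("A", "G"), c("G", "A"), c("T", "C"), c("C", "T"))[[sample(4, 1)]]
    oy <- one_variant_row(effect_allele = alleles[1], other_allele = alleles[2],
                          beta = rnorm(1), eaf = runif(1))
    h1 <- harmonize_pair(ex, oy)
    expect_identical(h1$action, "keep")
    expect_identical(h1$outcome$effect_allele, h1$exposure$effect_allele)
    h2 <- harmonize_pair(h1$exposure, h1$outcome)
    expect_equal(h2$outcome, h1$outcome)
  }
})

test_that("harmonize_tables drops incompatible variants with a reason", {
  ex <- sumstats(rbind(one_variant_row("rs1"),
                       one_variant_row("rs2", effect_allele = "C",
                                       other_allele = "T")), "x")
  oy <- sumstats(rbind(one_variant_row("rs1"),
                       one_variant_row("rs2", effect_allele = "C",
                                       other_allele = "G")), "y")
  h <- harmonize_tables(ex, oy)
  expect_identical(h$variant_id, "rs1")
  expect_match(attr(h, "dropped"), "rs2")
})
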