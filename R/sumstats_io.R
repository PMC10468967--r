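# Canonical per-variant schema shared by every module. Column types are
# enforced on read; `n` and `eaf` may be NA.
SUMSTATS_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pval", "n")

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary-statistics table
#'
#' Bundles a per-variant association data frame with trait metadata. This is
#' the container passed between all pipeline stages; each row is one
#' variant's association with the trait (effect size on the per-allele
#' scale, log-odds for binary traits).
#'
#' @param variants data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   Missing `eaf`/`n` columns are added as `NA`.
#' @param trait_id character scalar identifying the trait.
#' @param trait_type `"quantitative"` or `"binary"`. Binary traits must carry
#'   betas on the log-odds scale.
#' @param case_fraction optional case fraction for binary traits.
#' @param validate if `TRUE` (default) rows violating the per-variant
#'   invariants (positive SE, p in (0,1], distinct valid alleles, EAF in
#'   [0,1] or missing) are dropped with a message; the count of dropped rows
#'   is kept in `attr(, "n_rejected")`.
#'
#' @return An object of class `sumstats` (a list with elements `trait_id`,
#'   `trait_type`, `case_fraction` and `variants`).
#' @export
sumstats <- function(variants, trait_id, trait_type = c("quantitative", "binary"),
                     case_fraction = NA_real_, validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(variants), is.character(trait_id), length(trait_id) == 1L)
  for (col in c("eaf", "n")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_real_
  }
  missing_cols <- setdiff(SUMSTATS_COLUMNS, names(variants))
  if (length(missing_cols)) {
    stop("summary-statistics table for '", trait_id, "' is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  variants <- variants[SUMSTATS_COLUMNS]
  variants$variant_id <- as.character(variants$variant_id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$effect_allele <- toupper(as.character(variants$effect_allele))
  variants$other_allele <- toupper(as.character(variants$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    variants[[col]] <- as.numeric(variants[[col]])
  }

  n_rejected <- 0L
  if (validate && nrow(variants)) {
    ok <- variant_row_ok(variants)
    n_rejected <- sum(!ok)
    if (n_rejected > 0L) {
      reasons <- variant_row_reason(variants[!ok, , drop = FALSE])
      message(sprintf("sumstats('%s'): rejected %d row(s): %s", trait_id, n_rejected,
                      paste(unique(reasons), collapse = "; ")))
      variants <- variants[ok, , drop = FALSE]
    }
    if (anyDuplicated(variants$variant_id)) {
      stop("duplicate variant_id in table for '", trait_id, "'")
    }
  }
  rownames(variants) <- NULL
  structure(
    list(trait_id = trait_id, trait_type = trait_type,
         case_fraction = case_fraction, variants = variants),
    n_rejected = n_rejected,
    class = "sumstats"
  )
}

variant_row_ok <- function(v) {
  is.finite(v$se) & v$se > 0 &
    is.finite(v$pval) & v$pval > 0 & v$pval <= 1 &
    is.finite(v$beta) &
    v$effect_allele %in% VALID_ALLELES &
    v$other_allele %in% VALID_ALLELES &
    v$effect_allele != v$other_allele &
    (is.na(v$eaf) | (v$eaf >= 0 & v$eaf <= 1))
}

variant_row_reason <- function(v) {
  reason <- rep("invalid row", nrow(v))
  reason[!is.finite(v$se) | v$se <= 0] <- "non-positive SE"
  reason[!is.finite(v$pval) | v$pval <= 0 | v$pval > 1] <- "p-value outside (0,1]"
  reason[!(v$effect_allele %in% VALID_ALLELES) |
           !(v$other_allele %in% VALID_ALLELES)] <- "non-ACGT allele"
  reason[v$effect_allele == v$other_allele] <- "identical alleles"
  bad_eaf <- !is.na(v$eaf) & (v$eaf < 0 | v$eaf > 1)
  reason[bad_eaf] <- "EAF outside [0,1]"
  reason
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (%s), %d variant(s)\n",
              x$trait_id, x$trait_type, nrow(x$variants)))
  if (nrow(x$variants)) print(utils::head(x$variants, 6L))
  invisible(x)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited file with header into a [sumstats] object. Columns
#' may be renamed to the canonical schema through `column_map` (e.g.
#' `c(BETA = "beta", SNP = "variant_id")`). Rows failing the per-variant
#' invariants are dropped and counted; the count is available as
#' `attr(result, "n_rejected")`. Row order is preserved.
#'
#' @param path file path to a tab-delimited table with header; `"NA"` marks
#'   missing values.
#' @param trait_id trait identifier; defaults to the file name without
#'   extension.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param column_map named character vector mapping file headers to canonical
#'   field names.
#' @param case_fraction optional case fraction (binary traits).
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, trait_id = NULL,
                          trait_type = c("quantitative", "binary"),
                          column_map = NULL, case_fraction = NA_real_) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  if (is.null(trait_id)) trait_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  if (!is.null(column_map)) {
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- unname(column_map[names(df)[hit]])
  }
  missing_cols <- setdiff(setdiff(SUMSTATS_COLUMNS, c("eaf", "n")), names(df))
  if (length(missing_cols)) {
    stop("file '", path, "' lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sumstats(df, trait_id = trait_id, trait_type = trait_type,
           case_fraction = case_fraction)
}

#' Write a summary-statistics table
#'
#' Writes the canonical tab-delimited representation (header row, `"NA"` for
#' missing). `read_sumstats(write_sumstats(x, path))` reproduces `x`
#' field-by-field.
#'
#' @param table a [sumstats] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats"))
  utils::write.table(table$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complement_allele <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}

#' Harmonize one exposure/outcome variant pair to a shared effect allele
#'
#' Aligns the outcome association to the exposure's effect allele. Swapped
#' alleles flip the outcome beta (and EAF); strand flips (A<->T, C<->G
#' complements) are recognized and aligned without sign change; palindromic
#' variants (A/T or C/G) are dropped when the exposure EAF is missing or
#' within `palindrome_eaf_window` of 0.5, and otherwise oriented by matching
#' which side of 0.5 the two EAFs fall on.
#'
#' @param exposure,outcome single-row data frames (or lists) with the
#'   canonical per-variant fields, for the same `variant_id`.
#' @param palindrome_eaf_window half-width of the EAF ambiguity zone around
#'   0.5 inside which palindromic variants are dropped (default 0.08).
#' @return A list with `action` (`"keep"` or `"drop"`), `reason`, and when
#'   kept the aligned `exposure` and `outcome` rows (identical effect and
#'   other alleles).
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  exposure <- as.list(exposure)
  outcome <- as.list(outcome)
  if (!identical(as.character(exposure$variant_id), as.character(outcome$variant_id))) {
    stop("harmonize_pair() requires matching variant_id (got '",
         exposure$variant_id, "' vs '", outcome$variant_id, "')")
  }
  ea_x <- exposure$effect_allele; oa_x <- exposure$other_allele
  ea_y <- outcome$effect_allele;  oa_y <- outcome$other_allele

  if (is_palindromic(ea_x, oa_x)) {
    eaf_x <- exposure$eaf; eaf_y <- outcome$eaf
    if (is.na(eaf_x) || is.na(eaf_y) ||
        abs(eaf_x - 0.5) <= palindrome_eaf_window ||
        abs(eaf_y - 0.5) <= palindrome_eaf_window) {
      return(list(action = "drop", reason = "palindromic variant with ambiguous EAF"))
    }
    # Same allele letters on both strands: orient purely by EAF side.
    if (!setequal(c(ea_x, oa_x), c(ea_y, oa_y))) {
      return(list(action = "drop", reason = "incompatible alleles"))
    }
    same_side <- (eaf_x - 0.5) * (eaf_y - 0.5) > 0
    if (!same_side) {
      outcome$beta <- -outcome$beta
      outcome$eaf <- 1 - outcome$eaf
    }
    outcome$effect_allele <- ea_x
    outcome$other_allele <- oa_x
    return(list(action = "keep", reason = "palindromic, oriented by EAF",
                exposure = exposure, outcome = outcome))
  }

  align <- function(ey, oy) {
    if (ey == ea_x && oy == oa_x) return("same")
    if (ey == oa_x && oy == ea_x) return("swap")
    NA_character_
  }
  verdict <- align(ea_y, oa_y)
  flipped <- FALSE
  if (is.na(verdict)) {
    verdict <- align(complement_allele(ea_y), complement_allele(oa_y))
    flipped <- TRUE
  }
  if (is.na(verdict)) {
    return(list(action = "drop", reason = "incompatible alleles"))
  }
  if (verdict == "swap") {
    outcome$beta <- -outcome$beta
    if (!is.na(outcome$eaf)) outcome$eaf <- 1 - outcome$eaf
  }
  outcome$effect_allele <- ea_x
  outcome$other_allele <- oa_x
  list(action = "keep",
       reason = if (flipped) paste0("strand flip, ", verdict) else verdict,
       exposure = exposure, outcome = outcome)
}

#' Harmonize two summary-statistics tables over their shared variants
#'
#' Applies [harmonize_pair()] to every variant present in both tables and
#' returns the aligned per-variant effects needed by the MR estimators.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param palindrome_eaf_window passed to [harmonize_pair()].
#' @return A data frame with one row per retained shared variant:
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta_gx`, `se_gx`, `pval_gx`, `beta_gy`, `se_gy`, `pval_gy`.
#'   Dropped variants and reasons are stored in `attr(, "dropped")`.
#' @export
harmonize_tables <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- exposure$variants
  oy <- outcome$variants
  shared <- intersect(ex$variant_id, oy$variant_id)
  ex <- ex[match(shared, ex$variant_id), , drop = FALSE]
  oy <- oy[match(shared, oy$variant_id), , drop = FALSE]
  keep <- logical(length(shared))
  dropped <- character(0)
  out_rows <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    h <- harmonize_pair(ex[i, ], oy[i, ], palindrome_eaf_window)
    if (h$action == "keep") {
      keep[i] <- TRUE
      out_rows[[i]] <- data.frame(
        variant_id = h$exposure$variant_id,
        chrom = h$exposure$chrom,
        pos = h$exposure$pos,
        effect_allele = h$exposure$effect_allele,
        other_allele = h$exposure$other_allele,
        eaf = h$exposure$eaf,
        beta_gx = h$exposure$beta, se_gx = h$exposure$se, pval_gx = h$exposure$pval,
        beta_gy = h$outcome$beta, se_gy = h$outcome$se, pval_gy = h$outcome$pval,
        stringsAsFactors = FALSE)
    } else {
      dropped <- c(dropped, sprintf("%s (%s)", shared[i], h$reason))
    }
  }
  res <- if (any(keep)) do.call(rbind, out_rows[keep]) else
    data.frame(variant_id = character(0), chrom = character(0), pos = integer(0),
               effect_allele = character(0), other_allele = character(0),
               eaf = numeric(0),
               beta_gx = numeric(0), se_gx = numeric(0), pval_gx = numeric(0),
               beta_gy = numeric(0), se_gy = numeric(0), pval_gy = numeric(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}
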