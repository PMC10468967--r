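# Instrument screening at the four significance levels and greedy LD
# clumping down to independent representatives.

SCREENING_LEVELS <- c(e5 = 1e-5, e6 = 1e-6, e7 = 1e-7, e8 = 1e-8)

#' Screening level threshold
#'
#' The four instrument-screening significance levels `e5`..`e8`
#' (p < 1e-5 .. p < 1e-8).
#'
#' @param label one of `"e5"`, `"e6"`, `"e7"`, `"e8"`.
#' @return The p-value cutoff as a numeric scalar, named by its label.
#' @export
screening_level <- function(label) {
  label <- match.arg(label, names(SCREENING_LEVELS))
  SCREENING_LEVELS[label]
}

#' Screen candidate instruments by p-value
#'
#' Keeps exactly the variants with `pval` strictly below the level's cutoff,
#' preserving input order. Strict inequality: a p-value exactly at the
#' threshold is excluded.
#'
#' @param table a [sumstats] object.
#' @param level a level label (`"e5"`..`"e8"`) or a numeric cutoff.
#' @return Data frame of the retained variant rows (possibly empty).
#' @export
screen_by_pvalue <- function(table, level) {
  stopifnot(inherits(table, "sumstats"))
  threshold <- if (is.character(level)) screening_level(level) else as.numeric(level)
  v <- table$variants
  res <- v[v$pval < threshold, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a square LD matrix
#'
#' Tab-delimited square matrix of squared correlations with variant ids as
#' both header row and first column.
#'
#' @param path file path.
#' @return A symmetric numeric matrix with unit diagonal and dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1L,
                          sep = "\t", check.names = FALSE)
  m <- as.matrix(df)
  validate_ld_matrix(m)
  m
}

#' Write an LD matrix
#'
#' @param ld square matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  validate_ld_matrix(ld)
  df <- data.frame(variant_id = rownames(ld), ld, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_ld_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("LD matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("LD matrix must carry identical row/column variant ids")
  if (any(m < -1e-8 | m > 1 + 1e-8)) stop("LD r^2 values must lie in [0,1]")
  if (max(abs(m - t(m))) > 1e-8) stop("LD matrix must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-8)) stop("LD matrix diagonal must be 1")
  invisible(m)
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining candidate with the smallest p-value and
#' removes every other candidate with r-squared at or above `r2_threshold`
#' within `window_bp` of it. Ties on p are broken by smaller genomic
#' position, then lexicographic variant id, so the result is deterministic.
#' The output is pairwise below the threshold and re-clumping it is a
#' no-op.
#'
#' @param candidates data frame of variant rows (as from
#'   [screen_by_pvalue()]) with `variant_id`, `chrom`, `pos`, `pval`.
#' @param ld square r-squared matrix covering all candidates.
#' @param r2_threshold clumping r-squared cutoff (default 0.001).
#' @param window_bp clumping window in base pairs on each side
#'   (default 1e7).
#' @return The retained rows, in lead-selection order.
#' @export
ld_clump <- function(candidates, ld, r2_threshold = 0.001, window_bp = 1e7) {
  if (nrow(candidates) == 0L) return(candidates)
  missing_ids <- setdiff(candidates$variant_id, rownames(ld))
  if (length(missing_ids)) {
    stop("candidate variant(s) absent from LD matrix: ",
         paste(missing_ids, collapse = ", "))
  }
  ord <- order(candidates$pval, candidates$pos, candidates$variant_id)
  pool <- candidates[ord, , drop = FALSE]
  kept <- integer(0)
  alive <- rep(TRUE, nrow(pool))
  for (i in seq_len(nrow(pool))) {
    if (!alive[i]) next
    kept <- c(kept, i)
    lead <- pool[i, ]
    linked <- alive &
      pool$chrom == lead$chrom &
      abs(pool$pos - lead$pos) <= window_bp &
      ld[lead$variant_id, pool$variant_id] >= r2_threshold
    linked[i] <- TRUE
    alive[linked] <- FALSE
  }
  res <- pool[kept, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select LD-independent instruments at one screening level
#'
#' Convenience wrapper: screen a table at a level, then clump.
#'
#' @inheritParams screen_by_pvalue
#' @inheritParams ld_clump
#' @return Data frame of selected instruments.
#' @export
select_instruments <- function(table, level, ld, r2_threshold = 0.001,
                               window_bp = 1e7) {
  ld_clump(screen_by_pvalue(table, level), ld, r2_threshold, window_bp)
}
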