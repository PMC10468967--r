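# Full-analysis orchestration: screen -> clump -> harmonize -> univariable
# MR per level -> heterogeneity/pleiotropy filter -> Bonferroni on
# single-instrument (cis) results -> bi-directional mediation among
# survivors -> multivariable MR for multi-mediator exposures -> coloc for
# the top cis exposure.

#' Significance and heterogeneity/pleiotropy filter
#'
#' Keeps results with `p_mr < p_mr_max` AND no evidence of heterogeneity
#' (`Q_pval > q_pval_min`) AND no evidence of directional pleiotropy
#' (`p_pleio > p_pleio_min`). A diagnostic that is `NA` because the
#' instrument count cannot support it (Q needs k >= 2, the Egger intercept
#' k >= 3) counts as a pass. The filter is order-independent and
#' idempotent.
#'
#' @param results an `mr_result` data frame (see [run_univariable_mr()]).
#' @param p_mr_max MR significance threshold (default 0.05).
#' @param q_pval_min minimum Cochran-Q p-value (default 0.05).
#' @param p_pleio_min minimum Egger-intercept p-value (default 0.05).
#' @return The retained rows.
#' @export
apply_significance_filter <- function(results, p_mr_max = 0.05,
                                      q_pval_min = 0.05, p_pleio_min = 0.05) {
  if (nrow(results) == 0L) return(results)
  keep <- results$p_mr < p_mr_max &
    (is.na(results$Q_pval) | results$Q_pval > q_pval_min) &
    (is.na(results$p_pleio) | results$p_pleio > p_pleio_min)
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bonferroni adjustment
#'
#' `min(1, raw_p * family_size)`, the correction applied to
#' single-instrument (cis) MR p-values over the number of exposures tested
#' in the same class.
#'
#' @param raw_p raw p-value(s) in (0, 1].
#' @param family_size number of tests in the family (>= 1).
#' @return Adjusted p-value(s), capped at 1.
#' @examples
#' bonferroni_adjust(7.0e-4, 131)  # 0.0917
#' @export
bonferroni_adjust <- function(raw_p, family_size) {
  if (any(!is.finite(raw_p)) || any(raw_p <= 0) || any(raw_p > 1))
    stop("raw_p must lie in (0, 1]")
  if (!is.finite(family_size) || family_size < 1)
    stop("family_size must be >= 1")
  pmin(1, raw_p * family_size)
}

#' Run the full summary-statistics MR pipeline
#'
#' Executes every stage on in-memory data (as produced by
#' [simulate_exposure_outcome()] or read from files): univariable MR at
#' each screening level for every exposure; the significance +
#' heterogeneity/pleiotropy filter; Bonferroni adjustment of
#' single-instrument (cis) results over `family_size`; bi-directional
#' mediation MR among filter survivors (between the two exposure `groups`
#' when given, else among all survivors); multivariable MR for every
#' exposure whose effect is carried by two or more mediators (joint
#' mediator model plus the exposure's mediator-adjusted effect); and
#' colocalization of the top cis exposure (smallest Bonferroni-adjusted p)
#' against the outcome around its instrument. Each stage appends one
#' structured line to the run log.
#'
#' @param exposures named list of [sumstats] objects.
#' @param outcome a [sumstats] object.
#' @param ld LD r-squared matrix covering all exposure variants.
#' @param groups optional character vector (named by exposure id) of class
#'   labels; mediation pairs are drawn across the two classes when exactly
#'   two are present.
#' @param levels screening levels (default all four).
#' @param p_mr_max,q_pval_min,p_pleio_min filter thresholds (see
#'   [apply_significance_filter()]).
#' @param family_size Bonferroni family size for cis results (default:
#'   number of exposures).
#' @param retain_p multivariable-MR retention threshold (default 0.1).
#' @param coloc_window_bp,coloc_p1,coloc_p2,coloc_p12 colocalization
#'   settings.
#' @param outdir optional directory; when given, the report tables
#'   (`mr_results.tsv`, `mr_filtered.tsv`, `cis_bonferroni.tsv`,
#'   `mediation_triangles.tsv`, `mvmr_results.tsv`, `coloc_results.tsv`)
#'   and `run.log` are written there.
#' @param ... further arguments to [run_univariable_mr()].
#' @return A list with elements `mr_results`, `mr_filtered`,
#'   `cis_bonferroni`, `mediation`, `mvmr`, `coloc` and `log`.
#' @export
run_full <- function(exposures, outcome, ld, groups = NULL,
                     levels = names(SCREENING_LEVELS),
                     p_mr_max = 0.05, q_pval_min = 0.05, p_pleio_min = 0.05,
                     family_size = length(exposures), retain_p = 0.1,
                     coloc_window_bp = 50000L, coloc_p1 = 1e-4,
                     coloc_p2 = 1e-4, coloc_p12 = 1e-5,
                     outdir = NULL, ...) {
  log_lines <- character(0)
  log_stage <- function(stage, ...) {
    line <- sprintf("stage=%s %s", stage, paste(sprintf("%s=%s", names(list(...)),
                                                        unlist(list(...))),
                                                collapse = " "))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  # --- univariable MR per exposure and level ------------------------------
  mr_results <- list()
  for (id in names(exposures)) {
    res <- tryCatch(
      suppressMessages(run_univariable_mr(exposures[[id]], outcome, ld,
                                          levels = levels, ...)),
      error = function(e) stop("stage univariable_mr failed for '", id, "': ",
                               conditionMessage(e)))
    if (nrow(res)) mr_results[[id]] <- res
  }
  mr_results <- if (length(mr_results)) {
    out <- do.call(rbind, mr_results); rownames(out) <- NULL; out
  } else empty_mr_table()
  log_stage("univariable_mr", exposures = length(exposures),
            results = nrow(mr_results))

  # --- het/pleio significance filter --------------------------------------
  mr_filtered <- apply_significance_filter(mr_results, p_mr_max,
                                           q_pval_min, p_pleio_min)
  log_stage("significance_filter", input = nrow(mr_results),
            kept = nrow(mr_filtered), p_mr_max = p_mr_max)

  # --- Bonferroni over cis (single-instrument) results --------------------
  cis <- mr_results[mr_results$method == "wald_ratio", , drop = FALSE]
  if (nrow(cis)) {
    cis$p_adjusted <- bonferroni_adjust(cis$p_mr, family_size)
    cis <- cis[order(cis$p_adjusted), , drop = FALSE]
    rownames(cis) <- NULL
  } else {
    cis$p_adjusted <- numeric(0)
  }
  log_stage("bonferroni_cis", cis_results = nrow(cis),
            family_size = family_size)

  # --- bi-directional mediation among survivors ---------------------------
  survivors <- unique(mr_filtered$exposure)
  if (!is.null(groups) && length(unique(groups[survivors])) == 2L) {
    gl <- sort(unique(groups[survivors]))
    ids_a <- survivors[groups[survivors] == gl[1L]]
    ids_b <- survivors[groups[survivors] == gl[2L]]
  } else {
    ids_a <- ids_b <- survivors
  }
  mediation <- bidirectional_scan(exposures[ids_a], exposures[ids_b],
                                  outcome, ld, levels = levels[1L],
                                  edge_p = p_mr_max, ...)
  log_stage("mediation", exposures_a = length(ids_a),
            exposures_b = length(ids_b), triangles = nrow(mediation))

  # --- multivariable MR for multi-mediator exposures ----------------------
  mvmr_tabs <- list()
  if (nrow(mediation)) {
    med_ok <- mediation[mediation$direction_flag == "forward", , drop = FALSE]
    for (ex in unique(med_ok$exposure)) {
      mediators <- unique(med_ok$mediator[med_ok$exposure == ex])
      if (length(mediators) < 2L) next
      harmonized <- lapply(exposures[c(ex, mediators)], function(s) {
        iv <- select_instruments(s, levels[1L], ld)
        sub <- s; sub$variants <- iv
        harmonize_tables(sub, outcome)
      })
      fit <- tryCatch({
        joint <- mvmr_fit(mvmr_design(harmonized[mediators]), retain_p)
        adj <- mvmr_adjusted_effect(ex, mediators, harmonized)
        joint$adjusted_by <- NA_character_
        joint$role <- "mediator"
        adj$role <- "adjusted_exposure"
        rbind(joint, adj)
      }, error = function(e) {
        log_stage("mvmr_skip", exposure = ex, reason = conditionMessage(e))
        NULL
      })
      if (!is.null(fit)) {
        fit$primary_exposure <- ex
        mvmr_tabs[[ex]] <- fit
      }
    }
  }
  mvmr_results <- if (length(mvmr_tabs)) {
    out <- do.call(rbind, mvmr_tabs); rownames(out) <- NULL; out
  } else NULL
  log_stage("mvmr", models = length(mvmr_tabs))

  # --- colocalization for the top cis exposure ----------------------------
  coloc_result <- NULL
  if (nrow(cis)) {
    top <- cis[1L, ]
    top_exposure <- exposures[[top$exposure]]
    lead <- select_instruments(top_exposure, top$level, ld)$variant_id[1L]
    coloc_result <- tryCatch(
      coloc_region(top_exposure, outcome, lead, coloc_window_bp,
                   p1 = coloc_p1, p2 = coloc_p2, p12 = coloc_p12),
      error = function(e) {
        log_stage("coloc_skip", reason = conditionMessage(e))
        NULL
      })
    if (!is.null(coloc_result)) {
      log_stage("coloc", exposure = top$exposure, lead = lead,
                pp_h4 = sprintf("%.3f", coloc_result$pp["PP.H4"]))
    }
  } else {
    log_stage("coloc_skip", reason = "no cis results")
  }

  out <- list(mr_results = mr_results, mr_filtered = mr_filtered,
              cis_bonferroni = cis, mediation = mediation,
              mvmr = mvmr_results, coloc = coloc_result, log = log_lines)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

empty_mr_table <- function() {
  structure(
    data.frame(exposure = character(0), outcome = character(0),
               method = character(0), level = character(0), nsnp = integer(0),
               beta = numeric(0), se = numeric(0), or_ = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0), p_mr = numeric(0),
               Q = numeric(0), Q_df = integer(0), Q_pval = numeric(0),
               egger_intercept = numeric(0), egger_intercept_se = numeric(0),
               p_pleio = numeric(0), stringsAsFactors = FALSE),
    class = c("mr_result", "data.frame"))
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  wt(out$mr_results, "mr_results.tsv")
  wt(out$mr_filtered, "mr_filtered.tsv")
  wt(out$cis_bonferroni, "cis_bonferroni.tsv")
  wt(mediation_report(out$mediation), "mediation_triangles.tsv")
  if (!is.null(out$mvmr)) wt(out$mvmr, "mvmr_results.tsv")
  if (!is.null(out$coloc)) {
    pp <- as.data.frame(t(out$coloc$pp))
    pp$n_variants <- out$coloc$n_variants
    wt(pp, "coloc_results.tsv")
  }
  writeLines(out$log, file.path(outdir, "run.log"))
  invisible(outdir)
}
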