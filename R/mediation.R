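# Bi-directional mediation MR: product-of-coefficients proportion mediated
# and the scan that assembles exposure -> mediator -> outcome triangles.

#' Proportion of an effect transmitted through a mediator
#'
#' For an exposure E, mediator M and outcome O with MR effects `beta_EM`
#' (E on M), `beta_MO` (M on O) and total effect `beta_EO` (E on O), the
#' proportion mediated is the indirect effect over the total effect:
#' `rho_M = beta_EM * beta_MO / beta_EO`, returned as a percentage.
#' Values outside [0, 100] indicate inconsistent mediation (indirect and
#' total effects of opposite sign, or indirect exceeding total) and are
#' returned with a warning rather than suppressed.
#'
#' @param beta_EM MR effect of the exposure on the mediator.
#' @param beta_MO MR effect of the mediator on the outcome.
#' @param beta_EO total MR effect of the exposure on the outcome
#'   (must be non-zero).
#' @return The proportion mediated, in percent.
#' @examples
#' mediation_proportion(0.2, 0.5, 0.4)  # 25
#' @export
mediation_proportion <- function(beta_EM, beta_MO, beta_EO) {
  if (any(beta_EO == 0)) {
    stop("proportion mediated undefined: total effect beta_EO is zero")
  }
  rho <- 100 * beta_EM * beta_MO / beta_EO
  bad <- rho < 0 | rho > 100
  if (any(bad)) {
    warning("inconsistent mediation: proportion outside [0%, 100%] (",
            paste(sprintf("%.1f%%", rho[bad]), collapse = ", "), ")")
  }
  rho
}

#' Bi-directional mediation scan
#'
#' For every ordered pair of traits drawn from two candidate lists (all of
#' which should already be significant on the outcome), runs univariable MR
#' in both directions (A on B and B on A) and assembles a mediation triangle
#' whenever all three edges — exposure on mediator (E->M), mediator on
#' outcome (M->O), and exposure on outcome (E->O) — are significant at
#' `edge_p`. The direction flag records whether only E->M was significant
#' (`"forward"`), only M->E (`"reverse"`, no triangle assembled in that
#' orientation), or both (`"ambiguous"`; the triangle is reported but should
#' be excluded from mediation summaries).
#'
#' @param traits_A,traits_B named lists of [sumstats] objects; pairs are
#'   taken as (exposure from A, mediator from B).
#' @param outcome a [sumstats] object.
#' @param ld LD r-squared matrix covering all candidate instruments.
#' @param levels screening levels tried in order; the first level with
#'   instruments is used per trait pair (default `"e5"`).
#' @param edge_p per-edge significance gate (default 0.05, unadjusted).
#' @param ... further arguments passed to [run_univariable_mr()].
#' @return Data frame of triangles: exposure, mediator, outcome ids, the
#'   three edge betas and p-values, `rho_M` (percent) and `direction_flag`.
#' @export
bidirectional_scan <- function(traits_A, traits_B, outcome, ld,
                               levels = "e5", edge_p = 0.05, ...) {
  empty <- data.frame(exposure = character(0), mediator = character(0),
                      outcome = character(0),
                      beta_EM = numeric(0), p_EM = numeric(0),
                      beta_MO = numeric(0), p_MO = numeric(0),
                      beta_EO = numeric(0), p_EO = numeric(0),
                      rho_M = numeric(0), direction_flag = character(0),
                      stringsAsFactors = FALSE)
  if (!length(traits_A) || !length(traits_B)) return(empty)

  first_mr <- function(exposure, target) {
    res <- suppressMessages(
      run_univariable_mr(exposure, target, ld, levels = levels, ...))
    if (nrow(res) == 0L) NULL else res[1L, ]
  }

  rows <- list()
  for (ea in names(traits_A)) {
    E <- traits_A[[ea]]
    eo <- first_mr(E, outcome)
    for (mb in names(traits_B)) {
      if (identical(ea, mb)) next
      M <- traits_B[[mb]]
      em <- first_mr(E, M)           # forward edge E -> M
      me <- first_mr(M, E)           # reverse edge M -> E
      mo <- first_mr(M, outcome)
      fwd <- !is.null(em) && em$p_mr < edge_p
      rev <- !is.null(me) && me$p_mr < edge_p
      if (!fwd) next
      if (is.null(mo) || mo$p_mr >= edge_p) next
      if (is.null(eo) || eo$p_mr >= edge_p) next
      rho <- suppressWarnings(
        mediation_proportion(em$beta, mo$beta, eo$beta))
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = ea, mediator = mb, outcome = outcome$trait_id,
        beta_EM = em$beta, p_EM = em$p_mr,
        beta_MO = mo$beta, p_MO = mo$p_mr,
        beta_EO = eo$beta, p_EO = eo$p_mr,
        rho_M = rho,
        direction_flag = if (rev) "ambiguous" else "forward",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a mediation report table
#'
#' One row per triangle with the three edge betas, the proportion mediated
#' as a percentage to one decimal place (e.g. `"36.8%"`), and the direction
#' flag. Triangles with a proportion outside [0%, 100%] keep their sign and
#' gain an `inconsistent` marker.
#'
#' @param triangles data frame from [bidirectional_scan()].
#' @return Data frame ready for writing with `rho_M_pct` formatted.
#' @export
mediation_report <- function(triangles) {
  out <- triangles
  out$rho_M_pct <- sprintf("%.1f%%", triangles$rho_M)
  out$inconsistent <- triangles$rho_M < 0 | triangles$rho_M > 100
  out
}
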