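#' Percentages of regulated genes in a gene set
#'
#' Percentages are taken over the quantified member genes only (members with
#' a non-missing regulation call); unquantified members are excluded from
#' the denominator and reported separately.
#'
#' @param members Gene symbols of the set.
#' @param regulation A regulation table from [regulate()].
#' @return A list with `pct_up`, `pct_down`, `pct_regulated`, `n_quantified`,
#'   `n_members`, `n_unquantified`.
#' @export
percent_regulated <- function(members, regulation) {
  reg <- regulation[regulation$gene %in% members & !is.na(regulation$call), ]
  if (nrow(reg) == 0) {
    stop("no quantified genes in the gene set intersect the regulation table",
         call. = FALSE)
  }
  n <- nrow(reg)
  pct_up <- 100 * sum(reg$call == "up") / n
  pct_down <- 100 * sum(reg$call == "down") / n
  list(pct_up = pct_up, pct_down = pct_down,
       pct_regulated = pct_up + pct_down,
       n_quantified = n, n_members = length(members),
       n_unquantified = length(members) - sum(members %in% reg$gene))
}

#' Weighted Pathway Regulation
#'
#' A cut-off-free pathway score: each quantified member gene contributes
#' `c_i = (|x_i| - 1) * (1 - p_i)`, weighting regulation magnitude by its
#' significance; the score aggregates the contributions (mean by default, so
#' pathways of different sizes are comparable). A gene with a 2x change at
#' p = 0.01 contributes more than twice as much as a gene with a 1.5x change
#' at p = 0.05.
#'
#' @inheritParams percent_regulated
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return The WPR score (>= 0; 0 iff every member has |x| = 1 or p = 1).
#' @export
wpr <- function(members, regulation, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  reg <- regulation[regulation$gene %in% members & !is.na(regulation$x) &
                      !is.na(regulation$p), ]
  if (nrow(reg) == 0) {
    stop("no quantified genes in the gene set intersect the regulation table",
         call. = FALSE)
  }
  contrib <- wpr_contribution(reg$x, reg$p)
  if (aggregate == "mean") mean(contrib) else sum(contrib)
}

#' Per-gene contribution to the Weighted Pathway Regulation score
#'
#' @param x Signed expression ratio(s), |x| >= 1.
#' @param p P-value(s) in \[0, 1\].
#' @return `(|x| - 1) * (1 - p)`.
#' @export
wpr_contribution <- function(x, p) {
  (abs(x) - 1) * (1 - p)
}

#' Pathway Protection: percent reduction of WPR under protection
#'
#' @param wpr_unprotected WPR in the unprotected comparison (> 0).
#' @param wpr_protected WPR in the protected comparison.
#' @return `100 * (wpr_unprotected - wpr_protected) / wpr_unprotected`; may
#'   be negative when protection worsens the pathway; NA when the
#'   unprotected WPR is 0 (undefined).
#' @export
ppr <- function(wpr_unprotected, wpr_protected) {
  ifelse(wpr_unprotected > 0,
         100 * (wpr_unprotected - wpr_protected) / wpr_unprotected,
         NA_real_)
}

#' Transcriptomic Protection: percent reduction of the regulated fraction
#'
#' The default mode is the plain reduction
#' `100 * (pct_unprotected - pct_protected) / pct_unprotected`. The
#' side-effect-adjusted mode additionally subtracts from the protected arm's
#' credit the percentage of genes regulated by the protective treatment
#' alone.
#'
#' @param pct_unprotected Percent regulated in the unprotected comparison
#'   (> 0).
#' @param pct_protected Percent regulated in the protected comparison.
#' @param pct_side_effect Percent regulated by the treatment alone; only
#'   used when `adjust_side_effects = TRUE`.
#' @param adjust_side_effects Logical; default FALSE.
#' @return TPR in percent (NA when `pct_unprotected` is 0).
#' @export
tpr <- function(pct_unprotected, pct_protected, pct_side_effect = 0,
                adjust_side_effects = FALSE) {
  num <- pct_unprotected - pct_protected -
    if (adjust_side_effects) pct_side_effect else 0
  ifelse(pct_unprotected > 0, 100 * num / pct_unprotected, NA_real_)
}

#' Pathway-level protection scores for a panel of gene sets
#'
#' Computes percent regulated and WPR per pathway for the unprotected and
#' protected comparisons, and the protection quantifiers TPR and PPR per
#' pathway (attached to the protected comparison's row).
#'
#' @param gene_sets Named list of member-symbol vectors (e.g. from
#'   [read_gmt()]).
#' @param reg_unprotected,reg_protected Regulation tables from [regulate()]
#'   for the unprotected (e.g. COS vs CON) and protected (e.g. CES vs CEN)
#'   comparisons.
#' @param reg_side_effect Optional regulation table for the
#'   treatment-alone comparison (e.g. CEN vs CON), used when
#'   `adjust_side_effects = TRUE`.
#' @param aggregate WPR aggregation, see [wpr()].
#' @param adjust_side_effects See [tpr()].
#' @return Data frame with one row per (pathway, comparison): columns
#'   `pathway`, `comparison`, `pct_up`, `pct_down`, `pct_regulated`, `wpr`,
#'   `tpr`, `ppr`, `tpr_mode`, `n_quantified`, `n_members`.
#' @export
pathway_scores <- function(gene_sets, reg_unprotected, reg_protected,
                           reg_side_effect = NULL,
                           aggregate = c("mean", "sum"),
                           adjust_side_effects = FALSE) {
  aggregate <- match.arg(aggregate)
  if (adjust_side_effects && is.null(reg_side_effect)) {
    stop("side-effect adjustment requires `reg_side_effect`", call. = FALSE)
  }
  rows <- lapply(names(gene_sets), function(nm) {
    members <- gene_sets[[nm]]
    pu <- percent_regulated(members, reg_unprotected)
    pp <- percent_regulated(members, reg_protected)
    wu <- wpr(members, reg_unprotected, aggregate)
    wp <- wpr(members, reg_protected, aggregate)
    side <- if (adjust_side_effects) {
      percent_regulated(members, reg_side_effect)$pct_regulated
    } else 0
    rbind(
      data.frame(pathway = nm,
                 comparison = reg_unprotected$comparison[1],
                 pct_up = pu$pct_up, pct_down = pu$pct_down,
                 pct_regulated = pu$pct_regulated, wpr = wu,
                 tpr = NA_real_, ppr = NA_real_,
                 tpr_mode = NA_character_,
                 n_quantified = pu$n_quantified, n_members = pu$n_members,
                 stringsAsFactors = FALSE),
      data.frame(pathway = nm,
                 comparison = reg_protected$comparison[1],
                 pct_up = pp$pct_up, pct_down = pp$pct_down,
                 pct_regulated = pp$pct_regulated, wpr = wp,
                 tpr = tpr(pu$pct_regulated, pp$pct_regulated, side,
                           adjust_side_effects),
                 ppr = ppr(wu, wp),
                 tpr_mode = if (adjust_side_effects) "side_effect_adjusted"
                            else "plain",
                 n_quantified = pp$n_quantified, n_members = pp$n_members,
                 stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
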