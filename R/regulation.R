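#' Signed expression ratio between two conditions
#'
#' Returns `mu_b / mu_a` when the gene is at least as expressed in condition
#' B as in A, and `-mu_a / mu_b` otherwise, so |x| >= 1 always and negative
#' values denote down-regulation in B relative to A. Ties are oriented up by
#' convention (x = 1).
#'
#' @param mu_a,mu_b Positive mean expression levels (vectorized).
#' @return Signed ratio(s) x with |x| >= 1.
#' @export
expression_ratio <- function(mu_a, mu_b) {
  if (any(!is.finite(mu_a) | !is.finite(mu_b) | mu_a <= 0 | mu_b <= 0)) {
    stop("expression means must be positive and finite", call. = FALSE)
  }
  ifelse(mu_b >= mu_a, mu_b / mu_a, -mu_a / mu_b)
}

#' Flexible fold-change cut-off from condition variabilities
#'
#' The per-gene cut-off combines the technical noise and biological
#' variability of the two compared conditions:
#' `CUT = 1 + sqrt(CV_A^2 + CV_B^2)`. An optional chi-square mid-interval
#' correction inflates each CV for the small replicate count before
#' combining.
#'
#' @param cv_a,cv_b Nonnegative pooled coefficients of variation.
#' @param n_a,n_b Replicate counts (only used by the corrected estimator).
#' @param estimator `"plain"` (default) or `"chisq"` for the mid-interval
#'   corrected CV `cv * sqrt((n - 1) / qchisq(0.5, n - 1))`.
#' @return CUT value(s), always >= 1 and nondecreasing in each CV.
#' @export
compute_cut <- function(cv_a, cv_b, n_a = NULL, n_b = NULL,
                        estimator = c("plain", "chisq")) {
  estimator <- match.arg(estimator)
  if (any(cv_a < 0 | cv_b < 0, na.rm = TRUE)) {
    stop("coefficients of variation must be >= 0", call. = FALSE)
  }
  if (estimator == "chisq") {
    if (is.null(n_a) || is.null(n_b)) {
      stop("the chisq estimator needs replicate counts n_a, n_b",
           call. = FALSE)
    }
    cv_a <- cv_a * sqrt((n_a - 1) / stats::qchisq(0.5, n_a - 1))
    cv_b <- cv_b * sqrt((n_b - 1) / stats::qchisq(0.5, n_b - 1))
  }
  1 + sqrt(cv_a^2 + cv_b^2)
}

## Welch two-sample two-tailed t-test p-value, robust to zero variance.
welch_p <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Gene-level p-value with redundant-spot correction
#'
#' Applies a heteroscedastic (Welch) two-sample two-tailed t-test to each
#' distinct spot group probing the gene and combines them with a
#' Bonferroni-type correction: `p = min(1, k * min_j p_j)` over the k spot
#' groups (or the Sidak analogue `1 - (1 - min_j p_j)^k`).
#'
#' @param a,b Replicate values in the two conditions: numeric vectors for a
#'   single spot group, or matrices with one row per spot group and one
#'   column per replicate.
#' @param k Number of distinct spot groups probing the gene; defaults to the
#'   number of rows supplied.
#' @param correction `"bonferroni"` (default) or `"sidak"`.
#' @return Gene-level p-value in \[0, 1\] (NA when fewer than 3 replicates
#'   with data in either condition).
#' @export
gene_p_value <- function(a, b, k = NULL,
                         correction = c("bonferroni", "sidak")) {
  correction <- match.arg(correction)
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (nrow(a) != nrow(b)) {
    stop("spot-group matrices must have matching rows", call. = FALSE)
  }
  if (is.null(k)) k <- nrow(a)
  ## a gene whose means rest on < 3 replicates in either condition is excluded
  if (sum(colSums(!is.na(a)) > 0) < 3 || sum(colSums(!is.na(b)) > 0) < 3) {
    return(NA_real_)
  }
  p_j <- vapply(seq_len(nrow(a)), function(j) welch_p(a[j, ], b[j, ]),
                numeric(1))
  p_j <- p_j[!is.na(p_j)]
  if (length(p_j) == 0) return(NA_real_)
  p_min <- min(p_j)
  if (correction == "bonferroni") min(1, k * p_min)
  else 1 - (1 - p_min)^k
}

#' Call regulation from the signed ratio, per-gene cut-off and p-value
#'
#' A gene is called up-regulated when `x >= CUT` and `p < alpha`,
#' down-regulated when `x <= -CUT` and `p < alpha`, and unregulated
#' otherwise. Equality with the cut-off counts as regulated. A uniform
#' fold-change threshold (such as 1.5x) is deliberately not used.
#'
#' @param x Signed expression ratio(s), |x| >= 1.
#' @param cut Per-gene cut-off(s), >= 1.
#' @param p P-value(s).
#' @param alpha Significance level (default 0.05).
#' @return Character vector in `c("up", "down", "none")` (NA propagates).
#' @export
call_regulation <- function(x, cut, p, alpha = 0.05) {
  out <- rep(NA_character_, length(x))
  known <- !is.na(x) & !is.na(cut) & !is.na(p)
  out[known] <- "none"
  out[known & x >= cut & p < alpha] <- "up"
  out[known & x <= -cut & p < alpha] <- "down"
  out
}

#' ON/OFF call from per-condition validity
#'
#' A gene is quantifiable in a condition when it has valid data in at least
#' n - 1 of the n replicates, and absent when valid in at most 1. A gene
#' quantifiable in condition B but absent in A is "turned_on"; the mirror
#' case is "turned_off"; otherwise "expressed_both" (quantifiable in both)
#' or "absent_both".
#'
#' @param n_valid_a,n_valid_b Valid replicate counts in conditions A and B.
#' @param n_a,n_b Total replicate counts.
#' @return Character vector in
#'   `c("turned_on", "turned_off", "expressed_both", "absent_both")`.
#' @export
call_on_off <- function(n_valid_a, n_valid_b, n_a, n_b) {
  quant_a <- n_valid_a >= n_a - 1
  quant_b <- n_valid_b >= n_b - 1
  absent_a <- n_valid_a <= 1
  absent_b <- n_valid_b <= 1
  out <- rep("absent_both", length(n_valid_a))
  out[quant_a & quant_b] <- "expressed_both"
  out[quant_b & absent_a] <- "turned_on"
  out[quant_a & absent_b] <- "turned_off"
  out
}

#' Per-gene regulation calls between two conditions
#'
#' For every gene quantified in both conditions (valid in at least n - 1
#' replicates of each), computes the signed expression ratio, the flexible
#' per-gene fold-change cut-off, the heteroscedastic t-test p-value with
#' redundant-spot correction, and the resulting regulation call; ON/OFF
#' status is reported for all genes.
#'
#' @param em A normalized `expr_matrix` (from [normalize_spots()]); must
#'   carry `stats` (or they are computed on the fly).
#' @param numerator,denominator Condition names: the comparison is
#'   numerator vs denominator (e.g. COS vs CON).
#' @param alpha Significance level (default 0.05).
#' @param test_scale `"log"` (default) to t-test log-transformed levels, or
#'   `"linear"`.
#' @param cut_estimator Passed to [compute_cut()].
#' @param correction Passed to [gene_p_value()].
#' @return Data frame with columns `gene`, `comparison`, `x`, `cut`, `p`,
#'   `call`, `onoff`. `x`, `cut`, `p` and `call` are NA for genes not
#'   quantified in both conditions.
#' @export
regulate <- function(em, numerator, denominator, alpha = 0.05,
                     test_scale = c("log", "linear"),
                     cut_estimator = c("plain", "chisq"),
                     correction = c("bonferroni", "sidak")) {
  test_scale <- match.arg(test_scale)
  cut_estimator <- match.arg(cut_estimator)
  correction <- match.arg(correction)
  conds <- unique(em$samples$condition)
  if (!all(c(numerator, denominator) %in% conds)) {
    stop("comparison names conditions absent from the design: ",
         numerator, " vs ", denominator, call. = FALSE)
  }
  st <- em$stats
  if (is.null(st)) st <- condition_stats(em)
  sa <- st[st$condition == denominator, ]
  sb <- st[st$condition == numerator, ]
  genes <- rownames(em$values)
  sa <- sa[match(genes, sa$gene), ]
  sb <- sb[match(genes, sb$gene), ]

  onoff <- call_on_off(sa$n_valid, sb$n_valid, sa$n_replicates,
                       sb$n_replicates)

  cols_a <- em$samples$sample[em$samples$condition == denominator]
  cols_b <- em$samples$sample[em$samples$condition == numerator]
  ## with probe-level values, the test runs per redundant spot group; a
  ## matrix re-read from its TSV form only has the collapsed values, which
  ## then act as a single spot group (k = 1)
  have_probes <- !is.null(em$probe_values) && !is.null(em$probe_gene)
  if (have_probes) {
    pv_a <- em$probe_values[, cols_a, drop = FALSE]
    pv_b <- em$probe_values[, cols_b, drop = FALSE]
    probe_rows <- split(seq_along(em$probe_gene), em$probe_gene)
  } else {
    pv_a <- em$values[, cols_a, drop = FALSE]
    pv_b <- em$values[, cols_b, drop = FALSE]
    probe_rows <- split(seq_along(genes), genes)
  }
  if (test_scale == "log") {
    pv_a <- log(pv_a)
    pv_b <- log(pv_b)
  }

  x <- cut <- p <- rep(NA_real_, length(genes))
  usable <- sa$quantified & sb$quantified
  for (i in which(usable)) {
    rows <- probe_rows[[genes[i]]]
    x[i] <- expression_ratio(sa$mu[i], sb$mu[i])
    cut[i] <- compute_cut(sa$cv[i], sb$cv[i], sa$n_valid[i], sb$n_valid[i],
                          estimator = cut_estimator)
    p[i] <- gene_p_value(pv_a[rows, , drop = FALSE],
                         pv_b[rows, , drop = FALSE],
                         k = length(rows), correction = correction)
  }
  data.frame(
    gene = genes,
    comparison = paste0(numerator, "_vs_", denominator),
    x = x, cut = cut, p = p,
    call = call_regulation(x, cut, p, alpha),
    onoff = onoff,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
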