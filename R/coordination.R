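#' Number of unordered gene pairs
#'
#' @param n_genes Number of genes.
#' @return `n_genes * (n_genes - 1) / 2`.
#' @export
n_gene_pairs <- function(n_genes) {
  choose(n_genes, 2)
}

#' Critical Pearson correlation at significance alpha
#'
#' Exact critical value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`, appropriate at the very small
#' replicate counts of microarray designs (no Fisher-z asymptotics).
#'
#' @param n Number of replicates (>= 3).
#' @param alpha Two-tailed significance level (default 0.05).
#' @return The critical |r| above which the correlation is significant.
#' @export
r_critical <- function(n, alpha = 0.05) {
  if (any(n < 3)) stop("n must be >= 3", call. = FALSE)
  tc <- stats::qt(1 - alpha / 2, n - 2)
  tc / sqrt(tc^2 + n - 2)
}

## two-tailed p-value of r via the t transform
correlation_p <- function(r, n) {
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-t, n - 2)
}

#' Classify expression coordination of a gene pair
#'
#' S (synergistic) when r reaches the positive critical value at level
#' alpha, A (antagonistic) when it reaches the negative one, I (independent)
#' when |r| is at most `r_ind`, and U (undetermined) otherwise — too little
#' evidence at these replicate counts to call either way.
#'
#' @param r Pearson correlation(s) in \[-1, 1\].
#' @param n Replicate count(s).
#' @param alpha Significance level (default 0.05).
#' @param r_ind Independence threshold on |r| (default 0.25).
#' @return Character vector in `c("S", "A", "I", "U")` (NA propagates).
#' @export
classify_coordination <- function(r, n, alpha = 0.05, r_ind = 0.25) {
  rc <- r_critical(n, alpha)
  out <- rep(NA_character_, length(r))
  known <- !is.na(r)
  out[known] <- "U"
  out[known & abs(r) <= r_ind] <- "I"
  out[known & r >= rc] <- "S"
  out[known & r <= -rc] <- "A"
  out
}

#' Genes quantified in every replicate of given conditions
#'
#' @param em An `expr_matrix`.
#' @param conditions One or more condition names.
#' @return Gene symbols with valid values in all replicates of all the
#'   conditions; the shared pair universe for cross-condition switch
#'   detection.
#' @export
complete_genes <- function(em, conditions) {
  Reduce(intersect, lapply(conditions, function(cn) {
    cols <- em$samples$sample[em$samples$condition == cn]
    if (length(cols) == 0) stop("unknown condition: ", cn, call. = FALSE)
    rownames(em$values)[rowSums(is.na(em$values[, cols, drop = FALSE])) == 0]
  }))
}

#' Pairwise expression coordination within one condition
#'
#' Computes the Pearson correlation between the expression levels of every
#' unordered pair of genes across the biological replicates of one
#' condition, and classifies each pair. Only genes quantified in all
#' replicates of the condition enter; pairs involving a zero-variance gene
#' are marked uncomputable (NA class).
#'
#' @param em A normalized `expr_matrix`.
#' @param condition Condition name.
#' @param genes Optional subset of genes (default: all quantifiable).
#' @param alpha,r_ind See [classify_coordination()].
#' @param scale `"log"` (default) to correlate log levels, or `"linear"`.
#' @return Data frame of class `coordination_edges` with columns `gene_a`,
#'   `gene_b`, `condition`, `r`, `n`, `p_sig`, `class`, with gene_a < gene_b
#'   and exactly G(G-1)/2 rows for G genes.
#' @export
coordination_edges <- function(em, condition, genes = NULL, alpha = 0.05,
                               r_ind = 0.25, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  cols <- em$samples$sample[em$samples$condition == condition]
  if (length(cols) == 0) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  n <- length(cols)
  if (n < 3) stop("need >= 3 replicates", call. = FALSE)
  vals <- em$values[, cols, drop = FALSE]
  complete <- rownames(vals)[rowSums(is.na(vals)) == 0]
  genes <- if (is.null(genes)) complete else intersect(genes, complete)
  genes <- sort(genes)
  if (length(genes) < 2) {
    stop("fewer than 2 genes quantified in all replicates of ", condition,
         call. = FALSE)
  }
  m <- vals[genes, , drop = FALSE]
  if (scale == "log") m <- log(m)
  zero_var <- apply(m, 1, stats::sd) == 0
  suppressWarnings(rmat <- stats::cor(t(m)))
  idx <- which(upper.tri(rmat), arr.ind = TRUE)
  r <- rmat[idx]
  r[zero_var[idx[, 1]] | zero_var[idx[, 2]]] <- NA_real_
  out <- data.frame(
    gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
    condition = condition, r = r, n = n,
    p_sig = correlation_p(r, n),
    class = classify_coordination(r, n, alpha, r_ind),
    stringsAsFactors = FALSE
  )
  class(out) <- c("coordination_edges", class(out))
  out
}

#' Percentages of S/A/I pairs between two gene sets
#'
#' Counts only cross-set pairs (one gene from each set); genes present in
#' both sets are excluded from both, mirroring a three-layer network in
#' which common genes form their own layer. Percentages are over computable
#' cross pairs; the remainder to 100 is the undetermined class.
#'
#' @param set_a,set_b Gene symbol vectors.
#' @param edges Edge table from [coordination_edges()].
#' @return A list with `pct_s`, `pct_a`, `pct_i`, `pct_u`, `n_pairs`.
#' @export
cross_set_percentages <- function(set_a, set_b, edges) {
  common <- intersect(set_a, set_b)
  set_a <- setdiff(set_a, common)
  set_b <- setdiff(set_b, common)
  cross <- (edges$gene_a %in% set_a & edges$gene_b %in% set_b) |
    (edges$gene_a %in% set_b & edges$gene_b %in% set_a)
  e <- edges[cross & !is.na(edges$class), ]
  if (nrow(e) == 0) {
    stop("no computable cross-set pairs between the two gene sets",
         call. = FALSE)
  }
  n <- nrow(e)
  list(pct_s = 100 * sum(e$class == "S") / n,
       pct_a = 100 * sum(e$class == "A") / n,
       pct_i = 100 * sum(e$class == "I") / n,
       pct_u = 100 * sum(e$class == "U") / n,
       n_pairs = n)
}

#' Detect coordination switches between two conditions
#'
#' Compares the coordination class of every gene pair between two edge
#' tables over the same pair universe and reports the pairs whose class
#' changed, labelling synergistic-to-antagonistic (S_to_A) and
#' antagonistic-to-synergistic (A_to_S) switches explicitly. Pairs
#' uncomputable in either condition are excluded.
#'
#' @param edges_from,edges_to Edge tables from [coordination_edges()] for
#'   the two conditions, over the same pairs.
#' @return Data frame with columns `gene_a`, `gene_b`, `from_class`,
#'   `to_class`, `switch_type` (`"S_to_A"`, `"A_to_S"` or `"other"`), plus
#'   attribute `n_excluded` (uncomputable pairs).
#' @export
detect_switches <- function(edges_from, edges_to) {
  key_from <- paste(edges_from$gene_a, edges_from$gene_b)
  key_to <- paste(edges_to$gene_a, edges_to$gene_b)
  if (length(key_from) != length(key_to) || !setequal(key_from, key_to)) {
    stop("the two edge tables cover different pair universes", call. = FALSE)
  }
  edges_to <- edges_to[match(key_from, key_to), ]
  ok <- !is.na(edges_from$class) & !is.na(edges_to$class)
  changed <- ok & edges_from$class != edges_to$class
  out <- data.frame(
    gene_a = edges_from$gene_a[changed],
    gene_b = edges_from$gene_b[changed],
    from_class = edges_from$class[changed],
    to_class = edges_to$class[changed],
    stringsAsFactors = FALSE
  )
  out$switch_type <- ifelse(out$from_class == "S" & out$to_class == "A",
                            "S_to_A",
                            ifelse(out$from_class == "A" & out$to_class == "S",
                                   "A_to_S", "other"))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Per-gene census of coordination switches
#'
#' Groups switch records by gene, counting each pair under both of its
#' genes, so hub genes with many switched partners stand out.
#'
#' @param switches Output of [detect_switches()].
#' @return Data frame with columns `gene`, `n_s_to_a`, `n_a_to_s`,
#'   `n_other`, sorted by total switches, descending.
#' @export
switch_census <- function(switches) {
  long <- rbind(
    data.frame(gene = switches$gene_a, switch_type = switches$switch_type,
               stringsAsFactors = FALSE),
    data.frame(gene = switches$gene_b, switch_type = switches$switch_type,
               stringsAsFactors = FALSE)
  )
  if (nrow(long) == 0) {
    return(data.frame(gene = character(0), n_s_to_a = integer(0),
                      n_a_to_s = integer(0), n_other = integer(0)))
  }
  tab <- table(long$gene, factor(long$switch_type,
                                 levels = c("S_to_A", "A_to_S", "other")))
  out <- data.frame(gene = rownames(tab),
                    n_s_to_a = as.integer(tab[, "S_to_A"]),
                    n_a_to_s = as.integer(tab[, "A_to_S"]),
                    n_other = as.integer(tab[, "other"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-(out$n_s_to_a + out$n_a_to_s + out$n_other), out$gene), ]
}

#' Build a two-pathway coordination network through common genes
#'
#' Emits the edges that link one pathway (for instance estrogen signaling)
#' to another (a neurotransmission pathway) through the genes the two share:
#' edges run between the first set and the common genes and between the
#' common genes and the second set, keeping only determined classes
#' (S, A or I). Nodes are annotated with the regulation call of a chosen
#' comparison when a regulation table is supplied.
#'
#' @param set_a,set_b Gene symbol vectors for the two pathway layers.
#' @param common_genes Gene symbols forming the middle layer; expected to be
#'   a subset of the union of the two sets (offenders produce a warning).
#' @param edges Edge table from [coordination_edges()].
#' @param regulation Optional regulation table from [regulate()] for node
#'   annotation.
#' @return A list with `edges` (gene_a, gene_b, layer_pair, r, class) and
#'   `nodes` (gene, layer, call).
#' @export
build_network <- function(set_a, set_b, common_genes, edges,
                          regulation = NULL) {
  stray <- setdiff(common_genes, union(set_a, set_b))
  if (length(stray) > 0) {
    warning("common genes absent from both pathway sets: ",
            paste(stray, collapse = ", "))
  }
  layer_a <- setdiff(set_a, common_genes)
  layer_b <- setdiff(set_b, common_genes)
  pick <- function(s1, s2, label) {
    sel <- ((edges$gene_a %in% s1 & edges$gene_b %in% s2) |
              (edges$gene_a %in% s2 & edges$gene_b %in% s1)) &
      !is.na(edges$class) & edges$class != "U"
    e <- edges[sel, c("gene_a", "gene_b", "r", "class")]
    if (nrow(e) > 0) e$layer_pair <- label
    e
  }
  net_edges <- rbind(pick(layer_a, common_genes, "A-CG"),
                     pick(common_genes, layer_b, "CG-B"))
  rownames(net_edges) <- NULL
  node_genes <- unique(c(
    if (nrow(net_edges) > 0) c(net_edges$gene_a, net_edges$gene_b),
    common_genes))
  layer <- ifelse(node_genes %in% common_genes, "CG",
                  ifelse(node_genes %in% layer_a, "A", "B"))
  call <- rep("unquantified", length(node_genes))
  if (!is.null(regulation)) {
    idx <- match(node_genes, regulation$gene)
    known <- !is.na(idx) & !is.na(regulation$call[idx])
    call[known] <- regulation$call[idx][known]
  }
  list(edges = net_edges,
       nodes = data.frame(gene = node_genes, layer = layer, call = call,
                          stringsAsFactors = FALSE))
}
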