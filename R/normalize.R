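#' Filter microarray spots on the validity criterion
#'
#' A non-control spot is valid if its foreground fluorescence is at least
#' twice its background. Control spots and invalid spots are removed.
#'
#' @param spots Data frame with columns `array_id`, `probe_id`, `channel`,
#'   `gene`, `control_flag`, `fg`, `bg`.
#' @return The retained rows, with attribute `retention` (a list with counts
#'   of input, control, invalid and retained spots).
#' @export
validate_spots <- function(spots) {
  required <- c("array_id", "probe_id", "channel", "gene", "control_flag",
                "fg", "bg")
  missing <- setdiff(required, names(spots))
  if (length(missing) > 0) {
    stop("spot table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  neg <- which(spots$fg < 0 | spots$bg < 0)
  if (length(neg) > 0) {
    stop("negative fluorescence in spot table row(s): ",
         paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
  }
  is_ctrl <- as.logical(spots$control_flag)
  valid <- !is_ctrl & spots$fg >= 2 * spots$bg
  out <- spots[valid, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retention") <- list(
    n_input = nrow(spots),
    n_control = sum(is_ctrl),
    n_invalid = sum(!is_ctrl) - nrow(out),
    n_retained = nrow(out)
  )
  out
}

#' Normalize background-subtracted spots to the same-label array median
#'
#' For each valid spot, the normalized value is the background-subtracted
#' foreground divided by the median background-subtracted foreground of all
#' valid spots with the same label on the same array, so the median
#' normalized value in every (array, label) group is 1.
#'
#' @param spots Valid spots as returned by [validate_spots()].
#' @return The input with an added `value` column.
#' @export
normalize_within_label <- function(spots) {
  if (nrow(spots) == 0) stop("no valid spots to normalize", call. = FALSE)
  grp <- interaction(spots$array_id, spots$channel, drop = TRUE)
  net <- spots$fg - spots$bg
  med <- stats::ave(net, grp, FUN = stats::median)
  if (any(med <= 0)) {
    stop("non-positive median background-subtracted fluorescence in an ",
         "(array, label) group", call. = FALSE)
  }
  spots$value <- net / med
  spots
}

#' Collapse redundant spots into a per-gene, per-sample expression matrix
#'
#' Averages all valid spots probing the same gene within each sample
#' (array-channel, mapped to condition and replicate by the design). Also
#' retains the per-probe values so that downstream tests can apply the
#' redundant-spot correction and fold spot-to-spot spread into the
#' variability estimate.
#'
#' @param spots Normalized spots from [normalize_within_label()].
#' @param design Data frame with columns `array_id`, `channel`, `condition`,
#'   `replicate`.
#' @return An object of class `expr_matrix`: a list with
#'   \describe{
#'     \item{values}{genes x samples matrix of expression levels (NA where no
#'       valid spot).}
#'     \item{mask}{genes x samples logical validity mask.}
#'     \item{samples}{data.frame of sample ids with condition and replicate.}
#'     \item{probe_values}{probes x samples matrix of per-spot-group values.}
#'     \item{probe_gene}{named character vector mapping probe_id to gene.}
#'   }
#' @export
collapse_redundancy <- function(spots, design) {
  need <- c("array_id", "channel", "condition", "replicate")
  if (!all(need %in% names(design))) {
    stop("design table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(design$array_id, design$channel)
  sample_id <- paste0(design$condition, "_r", design$replicate)
  skey <- paste(spots$array_id, spots$channel)
  idx <- match(skey, key)
  if (anyNA(idx)) {
    stop("spot table contains (array, channel) pairs absent from the design",
         call. = FALSE)
  }
  spots$sample <- sample_id[idx]
  samples <- unique(data.frame(sample = sample_id,
                               condition = design$condition,
                               replicate = design$replicate,
                               stringsAsFactors = FALSE))
  samples <- samples[order(match(samples$condition,
                                 unique(design$condition)),
                           samples$replicate), ]
  rownames(samples) <- NULL

  genes <- sort(unique(spots$gene))
  probes <- sort(unique(spots$probe_id))
  pv <- matrix(NA_real_, length(probes), nrow(samples),
               dimnames = list(probes, samples$sample))
  pv[cbind(match(spots$probe_id, probes), match(spots$sample, samples$sample))] <-
    spots$value
  probe_gene <- spots$gene[match(probes, spots$probe_id)]
  names(probe_gene) <- probes

  gi <- factor(probe_gene, levels = genes)
  values <- apply(pv, 2, function(col) {
    tapply(col, gi, function(v) if (all(is.na(v))) NA_real_
           else mean(v, na.rm = TRUE))
  })
  values <- matrix(unlist(values), length(genes), nrow(samples),
                   dimnames = list(genes, samples$sample))
  structure(list(values = values, mask = !is.na(values), samples = samples,
                 probe_values = pv, probe_gene = probe_gene),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d conditions), %d probes\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$condition)), nrow(x$probe_values)))
  invisible(x)
}

## Per-gene cross-condition expression ratios mu_B/mu_A for every ordered
## condition pair with A before B in the sample table; the units the
## convergence metric is defined on.
cross_condition_ratios <- function(em) {
  conds <- unique(em$samples$condition)
  mu <- vapply(conds, function(cn) {
    cols <- em$samples$sample[em$samples$condition == cn]
    rowMeans(em$values[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(em$values)))
  if (length(conds) < 2) {
    stop("need >= 2 conditions to form expression ratios", call. = FALSE)
  }
  pairs <- utils::combn(length(conds), 2)
  ratios <- mu[, pairs[2, ], drop = FALSE] / mu[, pairs[1, ], drop = FALSE]
  ratios[!is.finite(ratios)] <- NA_real_
  ratios
}

#' Iteratively renormalize samples across labels and conditions
#'
#' Alternately rescales every sample by the median ratio of its per-gene
#' values to a per-gene reference (the geometric mean across all samples in
#' which the gene is valid), recomputing the reference each pass, until the
#' average absolute relative change of all per-gene cross-condition
#' expression ratios between successive iterations falls below `tol`.
#'
#' @param em An `expr_matrix` from [collapse_redundancy()].
#' @param tol Convergence tolerance on the mean absolute relative ratio
#'   change (default 0.05, i.e. 5%).
#' @param max_iter Maximum number of iterations (default 100).
#' @return The renormalized `expr_matrix`, with attributes `iterations`,
#'   `final_delta` (the mean absolute relative ratio change at termination)
#'   and `deltas` (per-iteration trace). The probe-level values are rescaled
#'   by the same per-sample factors as the collapsed matrix.
#' @export
iterative_renormalize <- function(em, tol = 0.05, max_iter = 100) {
  if (ncol(em$values) < 2) stop("need >= 2 samples", call. = FALSE)
  ratios_old <- cross_condition_ratios(em)
  deltas <- numeric(0)
  for (it in seq_len(max_iter)) {
    ref <- exp(rowMeans(log(em$values), na.rm = TRUE))
    fac <- apply(em$values / ref, 2, stats::median, na.rm = TRUE)
    if (any(!is.finite(fac) | fac <= 0)) {
      stop("degenerate renormalization factor encountered", call. = FALSE)
    }
    em$values <- sweep(em$values, 2, fac, "/")
    em$probe_values <- sweep(em$probe_values, 2, fac, "/")
    ratios_new <- cross_condition_ratios(em)
    delta <- mean(abs(ratios_new / ratios_old - 1), na.rm = TRUE)
    deltas <- c(deltas, delta)
    ratios_old <- ratios_new
    if (delta < tol) {
      attr(em, "iterations") <- it
      attr(em, "final_delta") <- delta
      attr(em, "deltas") <- deltas
      return(em)
    }
  }
  stop(sprintf(
    "iterative renormalization did not converge in %d iterations (last mean relative ratio change %.4g)",
    max_iter, deltas[length(deltas)]), call. = FALSE)
}

#' Per-gene, per-condition summary statistics
#'
#' For each gene and condition: the mean normalized expression over valid
#' replicates, the replicate count with valid data, and a coefficient of
#' variation that pools biological spread among replicate means with the
#' technical spot-to-spot spread (folded in through the per-replicate
#' standard error of the redundant spots).
#'
#' @param em A (renormalized) `expr_matrix`.
#' @return Data frame with columns `gene`, `condition`, `mu`, `cv`,
#'   `n_valid`, `quantified` (valid in at least n - 1 replicates).
#' @export
condition_stats <- function(em) {
  conds <- unique(em$samples$condition)
  genes <- rownames(em$values)
  gi <- factor(em$probe_gene, levels = genes)
  out <- lapply(conds, function(cn) {
    cols <- em$samples$sample[em$samples$condition == cn]
    n_rep <- length(cols)
    vals <- em$values[, cols, drop = FALSE]
    n_valid <- rowSums(!is.na(vals))
    mu <- rowMeans(vals, na.rm = TRUE)
    mu[n_valid == 0] <- NA_real_
    ## technical variance: mean over replicates of se_i^2 where
    ## se_i^2 = var(spot values)/k_i within replicate i
    se2 <- vapply(cols, function(sc) {
      v <- em$probe_values[, sc]
      tapply(v, gi, function(x) {
        x <- x[!is.na(x)]
        if (length(x) <= 1) 0 else stats::var(x) / length(x)
      })
    }, numeric(length(genes)))
    se2_mean <- rowMeans(se2, na.rm = TRUE)
    bio_var <- apply(vals, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) <= 1) NA_real_ else stats::var(v)
    })
    cv <- sqrt(bio_var + se2_mean) / mu
    data.frame(gene = genes, condition = cn, mu = mu, cv = cv,
               n_valid = n_valid, n_replicates = n_rep,
               quantified = n_valid >= n_rep - 1,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Normalize a raw spot table end to end
#'
#' Chains validity filtering, background subtraction with per-label median
#' normalization, redundancy collapsing, and iterative cross-condition
#' renormalization, then attaches per-gene per-condition statistics.
#'
#' @inheritParams validate_spots
#' @inheritParams collapse_redundancy
#' @inheritParams iterative_renormalize
#' @return A converged `expr_matrix` with an added `stats` element
#'   (see [condition_stats()]).
#' @export
normalize_spots <- function(spots, design, tol = 0.05, max_iter = 100) {
  valid <- validate_spots(spots)
  norm <- normalize_within_label(valid)
  em <- collapse_redundancy(norm, design)
  em <- iterative_renormalize(em, tol = tol, max_iter = max_iter)
  em$stats <- condition_stats(em)
  em
}
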