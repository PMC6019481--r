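#' Simulation configuration for a synthetic two-channel microarray experiment
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The defaults emulate a 4 x 44k-style two-channel experiment in the
#' "multiple yellow" design: four conditions (CON, CEN, COS, CES) with four
#' biological replicates each, two differently labeled replicates of the same
#' condition co-hybridized per array, redundant spots per gene, lognormal
#' expression with per-gene biological variability, multiplicative label bias
#' and spot-level technical noise.
#'
#' Default planted regulation mirrors the study conditions the pipeline is
#' meant to analyse: 44% of genes regulated in COS vs CON (the insult without
#' protection) and 11% in CES vs CEN (the insult under protection), with
#' absolute fold changes uniform in \[1.5, 3\] and 60% of regulated genes
#' down-regulated. Default coordination blocks plant one synergistic and one
#' mixed-sign latent-factor block, the latter flipping sign in CES so that
#' coordination switches exist.
#'
#' @param n_genes Number of distinct genes (default 1000).
#' @param conditions Condition names; default `c("CON","CEN","COS","CES")`.
#' @param n_replicates Biological replicates per condition (default 4).
#' @param spots_per_gene Either a single count or a length-2 range from which
#'   each gene's number of redundant spots is drawn (default `c(1, 4)`).
#' @param control_spot_fraction Fraction of spots on the array that are
#'   controls (default 0.05).
#' @param background_mean Mean background fluorescence (default 50).
#' @param expression_log_mean_range Range (natural log fluorescence units) of
#'   per-gene baseline log expression (default `c(6, 10)`).
#' @param biological_cv_range Range of per-gene coefficients of variation
#'   among biological replicates (default `c(0.10, 0.50)`).
#' @param technical_cv Spot-level multiplicative noise CV (default 0.10).
#' @param planted_regulation `NULL` for the default plan described above, an
#'   empty data.frame for no regulation, or a data.frame with columns
#'   `gene`, `comparison` (e.g. `"COS_vs_CON"`) and signed `fold_change`
#'   (|fold change| >= 1, negative = down-regulation).
#' @param planted_correlation_blocks `NULL` for the default blocks, `list()`
#'   for none, or a list of blocks, each a list with elements `genes`
#'   (symbols), `loadings` (scalar or per-gene numeric, log-scale), `sigma2`
#'   (residual log-scale variance, >= 0) and optionally `flip_genes` (a
#'   subset of the block's genes) with `flip_conditions` (conditions in
#'   which those genes' loadings are negated, turning their pairs with the
#'   rest of the block from synergistic to antagonistic — the substrate of
#'   coordination switches).
#' @param label_bias_factors Named per-channel multiplicative scale factors
#'   (default `c(Cy3 = 1, Cy5 = 1.25)`); names define the channel labels.
#' @param invalid_spot_fraction Fraction of non-control spots forced below
#'   the validity threshold fg < 2 bg (default 0.01).
#' @param gene_names Optional vector of gene symbols to use (recycled from
#'   the packaged pathway fixture and padded with synthetic symbols when
#'   `NULL`, so that pathway-level analyses of simulated data are non-empty).
#' @param seed Integer seed governing every stochastic draw (default 1).
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(n_genes = 1000,
                       conditions = c("CON", "CEN", "COS", "CES"),
                       n_replicates = 4,
                       spots_per_gene = c(1, 4),
                       control_spot_fraction = 0.05,
                       background_mean = 50,
                       expression_log_mean_range = c(6, 10),
                       biological_cv_range = c(0.10, 0.50),
                       technical_cv = 0.10,
                       planted_regulation = NULL,
                       planted_correlation_blocks = NULL,
                       label_bias_factors = c(Cy3 = 1, Cy5 = 1.25),
                       invalid_spot_fraction = 0.01,
                       gene_names = NULL,
                       seed = 1L) {
  stop_field <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid config: `%s` %s", field, why), call. = FALSE)
  }
  stop_field(is.numeric(n_genes) && length(n_genes) == 1 && n_genes >= 1,
             "n_genes", "must be a count >= 1")
  n_genes <- as.integer(n_genes)
  stop_field(is.character(conditions) && length(conditions) >= 2 &&
               !anyDuplicated(conditions), "conditions",
             "must be >= 2 distinct names")
  stop_field(is.numeric(n_replicates) && n_replicates >= 1,
             "n_replicates", "must be a count >= 1")
  n_replicates <- as.integer(n_replicates)
  stop_field(is.numeric(spots_per_gene) && length(spots_per_gene) %in% 1:2 &&
               all(spots_per_gene >= 1), "spots_per_gene",
             "must be a count or range >= 1")
  if (length(spots_per_gene) == 1) spots_per_gene <- rep(spots_per_gene, 2)
  spots_per_gene <- as.integer(sort(spots_per_gene))
  stop_field(is.numeric(control_spot_fraction) &&
               control_spot_fraction >= 0 && control_spot_fraction < 1,
             "control_spot_fraction", "must be in [0, 1)")
  stop_field(is.numeric(background_mean) && background_mean > 0,
             "background_mean", "must be positive")
  stop_field(is.numeric(expression_log_mean_range) &&
               length(expression_log_mean_range) == 2 &&
               diff(expression_log_mean_range) >= 0,
             "expression_log_mean_range", "must be a nondecreasing range")
  stop_field(is.numeric(biological_cv_range) &&
               length(biological_cv_range) == 2 &&
               all(biological_cv_range >= 0) &&
               diff(biological_cv_range) >= 0,
             "biological_cv_range", "must be a nonnegative range")
  stop_field(is.numeric(technical_cv) && technical_cv >= 0,
             "technical_cv", "must be >= 0")
  stop_field(is.numeric(label_bias_factors) && length(label_bias_factors) == 2 &&
               all(label_bias_factors > 0) &&
               !is.null(names(label_bias_factors)),
             "label_bias_factors", "must be two named positive factors")
  stop_field(is.numeric(invalid_spot_fraction) &&
               invalid_spot_fraction >= 0 && invalid_spot_fraction < 1,
             "invalid_spot_fraction", "must be in [0, 1)")
  stop_field(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "seed", "must be a finite integer")
  seed <- as.integer(seed)

  if (is.null(gene_names)) gene_names <- default_gene_universe(n_genes)
  stop_field(length(gene_names) == n_genes && !anyDuplicated(gene_names),
             "gene_names", "must hold n_genes distinct symbols")

  if (is.null(planted_regulation)) {
    planted_regulation <- default_regulation_plan(gene_names, conditions, seed)
  }
  planted_regulation <- validate_regulation_plan(planted_regulation, gene_names)

  if (is.null(planted_correlation_blocks)) {
    planted_correlation_blocks <-
      default_correlation_blocks(gene_names, conditions)
  }
  planted_correlation_blocks <-
    validate_correlation_blocks(planted_correlation_blocks, gene_names,
                                conditions)

  structure(list(
    n_genes = n_genes, conditions = conditions, n_replicates = n_replicates,
    spots_per_gene = spots_per_gene,
    control_spot_fraction = control_spot_fraction,
    background_mean = background_mean,
    expression_log_mean_range = expression_log_mean_range,
    biological_cv_range = biological_cv_range,
    technical_cv = technical_cv,
    planted_regulation = planted_regulation,
    planted_correlation_blocks = planted_correlation_blocks,
    label_bias_factors = label_bias_factors,
    invalid_spot_fraction = invalid_spot_fraction,
    gene_names = gene_names, seed = seed
  ), class = "sim_config")
}

#' Default gene universe for simulations
#'
#' Uses the packaged pathway fixture's member genes first (so simulated data
#' intersect the pathway gene sets), padded with synthetic symbols.
#'
#' @param n_genes Number of symbols required.
#' @return Character vector of length `n_genes`.
#' @keywords internal
default_gene_universe <- function(n_genes) {
  gmt <- system.file("extdata", "pathways.gmt", package = "pathprotect")
  pool <- character(0)
  if (nzchar(gmt)) {
    sets <- read_gmt(gmt)
    ## round-robin across the sets so that any prefix of the universe
    ## covers every pathway
    depth <- max(lengths(sets))
    pool <- unlist(lapply(seq_len(depth), function(i) {
      vapply(sets, function(m) if (i <= length(m)) m[i] else NA_character_,
             character(1))
    }), use.names = FALSE)
    pool <- unique(pool[!is.na(pool)])
  }
  if (length(pool) >= n_genes) return(pool[seq_len(n_genes)])
  pad <- sprintf("Synth%04d", seq_len(n_genes - length(pool)))
  c(pool, pad)
}

# Default planted regulation: 44% of genes in COS_vs_CON, 11% in CES_vs_CEN,
# |FC| ~ U(1.5, 3), 60% down-regulated. Drawn from a seed-derived stream that
# does not disturb the generator's main stream.
default_regulation_plan <- function(genes, conditions, seed) {
  if (!all(c("CON", "CEN", "COS", "CES") %in% conditions)) {
    return(data.frame(gene = character(0), comparison = character(0),
                      fold_change = numeric(0)))
  }
  n <- length(genes)
  plan_one <- function(frac, comparison, rng_offset) {
    k <- round(frac * n)
    if (k == 0) return(NULL)
    st <- local({
      old <- get0(".Random.seed", globalenv(), inherits = FALSE)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
              else rm(".Random.seed", envir = globalenv()))
      set.seed((seed + rng_offset) %% .Machine$integer.max)
      g <- sample(genes, k)
      fc <- stats::runif(k, 1.5, 3) * ifelse(stats::runif(k) < 0.6, -1, 1)
      data.frame(gene = g, comparison = comparison, fold_change = fc)
    })
    st
  }
  plan <- rbind(plan_one(0.44, "COS_vs_CON", 101L),
                plan_one(0.11, "CES_vs_CEN", 202L))
  if (is.null(plan)) plan <- data.frame(gene = character(0),
                                        comparison = character(0),
                                        fold_change = numeric(0))
  plan
}

default_correlation_blocks <- function(genes, conditions) {
  if (length(genes) < 16) return(list())
  syn <- genes[seq_len(8)]
  mix <- genes[9:16]
  list(
    list(genes = syn, loadings = 1, sigma2 = 0.02),
    ## half of this block changes sides in CES, so gene pairs across the
    ## two halves switch from synergistic to antagonistic coordination
    list(genes = mix, loadings = 1, sigma2 = 0.02,
         flip_genes = mix[1:4],
         flip_conditions = intersect("CES", conditions))
  )
}

validate_regulation_plan <- function(plan, genes) {
  if (!is.data.frame(plan) ||
      !all(c("gene", "comparison", "fold_change") %in% names(plan))) {
    stop("invalid config: `planted_regulation` must be a data.frame with ",
         "columns gene, comparison, fold_change", call. = FALSE)
  }
  if (nrow(plan) == 0) return(plan)
  if (!all(plan$gene %in% genes)) {
    stop("invalid config: `planted_regulation` names unknown genes",
         call. = FALSE)
  }
  if (any(abs(plan$fold_change) < 1)) {
    stop("invalid config: `planted_regulation` fold_change must satisfy ",
         "|fold change| >= 1", call. = FALSE)
  }
  if (anyDuplicated(plan[, c("gene", "comparison")])) {
    stop("invalid config: `planted_regulation` has duplicate ",
         "(gene, comparison) rows", call. = FALSE)
  }
  plan
}

validate_correlation_blocks <- function(blocks, genes, conditions) {
  if (!is.list(blocks)) {
    stop("invalid config: `planted_correlation_blocks` must be a list",
         call. = FALSE)
  }
  seen <- character(0)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (!all(c("genes", "loadings", "sigma2") %in% names(b))) {
      stop("invalid config: correlation block ", i,
           " needs genes, loadings, sigma2", call. = FALSE)
    }
    if (!all(b$genes %in% genes)) {
      stop("invalid config: correlation block ", i, " names unknown genes",
           call. = FALSE)
    }
    if (any(b$genes %in% seen)) {
      stop("invalid config: gene assigned to more than one correlation block",
           call. = FALSE)
    }
    seen <- c(seen, b$genes)
    if (length(b$loadings) == 1) {
      blocks[[i]]$loadings <- rep(b$loadings, length(b$genes))
    } else if (length(b$loadings) != length(b$genes)) {
      stop("invalid config: block ", i, " loadings length mismatch",
           call. = FALSE)
    }
    if (!all(is.finite(blocks[[i]]$loadings))) {
      stop("invalid config: block ", i, " loadings must be finite",
           call. = FALSE)
    }
    if (!is.numeric(b$sigma2) || b$sigma2 < 0) {
      stop("invalid config: block ", i, " sigma2 must be >= 0", call. = FALSE)
    }
    if (is.null(b$flip_genes)) blocks[[i]]$flip_genes <- character(0)
    else if (!all(b$flip_genes %in% b$genes)) {
      stop("invalid config: block ", i,
           " flip_genes must be a subset of its genes", call. = FALSE)
    }
    if (is.null(b$flip_conditions)) blocks[[i]]$flip_conditions <- character(0)
    else if (!all(b$flip_conditions %in% conditions)) {
      stop("invalid config: block ", i,
           " flip_conditions names unknown conditions", call. = FALSE)
    }
  }
  blocks
}

## signed loadings of a block in one condition: flip_genes are negated in
## flip_conditions
block_loadings <- function(block, condition) {
  l <- block$loadings
  if (condition %in% block$flip_conditions) {
    l[block$genes %in% block$flip_genes] <- -l[block$genes %in% block$flip_genes]
  }
  l
}

#' Plant coordinated expression through a shared latent factor
#'
#' Generates per-replicate log-scale deviations for a block of genes that
#' load on one latent factor: gene i in replicate r receives
#' `loadings[i] * f[r] + sqrt(sigma2) * noise`. Two genes with loadings a and
#' b then have expected Pearson correlation
#' `a * b / sqrt((a^2 + sigma2) * (b^2 + sigma2))` across replicates.
#'
#' @param loadings Finite numeric loadings, one per gene.
#' @param n_replicates Number of replicates (>= 3; fewer make the downstream
#'   correlation undefined).
#' @param sigma2 Residual variance (>= 0).
#' @param factor Optional latent factor values, one per replicate (drawn
#'   standard normal when `NULL`).
#' @return Matrix of deviations, genes x replicates.
#' @examples
#' set.seed(1)
#' d <- plant_coordination(c(1, 1), n_replicates = 1e4, sigma2 = 1)
#' cor(d[1, ], d[2, ])  # close to 0.5
#' @export
plant_coordination <- function(loadings, n_replicates, sigma2 = 0,
                               factor = NULL) {
  if (!all(is.finite(loadings))) {
    stop("loadings must be finite", call. = FALSE)
  }
  if (n_replicates < 3) {
    stop("n_replicates must be >= 3: correlation across replicates is ",
         "undefined otherwise", call. = FALSE)
  }
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (is.null(factor)) factor <- stats::rnorm(n_replicates)
  if (length(factor) != n_replicates) {
    stop("factor must have one value per replicate", call. = FALSE)
  }
  g <- length(loadings)
  outer(loadings, factor) +
    sqrt(sigma2) * matrix(stats::rnorm(g * n_replicates), g, n_replicates)
}

#' Expected correlation planted by a shared latent factor
#'
#' @param a,b Loadings of the two genes.
#' @param sigma2 Residual variance.
#' @return The closed-form Pearson correlation.
#' @export
planted_correlation <- function(a, b, sigma2 = 0) {
  a * b / sqrt((a^2 + sigma2) * (b^2 + sigma2))
}

#' Generate a synthetic two-channel microarray experiment
#'
#' Emits a spot-level table, a design table mapping arrays and channels to
#' conditions and replicates, and ground-truth tables for parameter-recovery
#' testing. Each array co-hybridizes two differently labeled biological
#' replicates of the same condition (multiple-yellow design); each gene is
#' probed by a fixed set of redundant spots shared across arrays; spot
#' foreground is true level x label bias x lognormal technical noise +
#' background, and a configured fraction of spots is forced invalid
#' (fg < 2 bg).
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_experiment` with elements `spots` (data.frame:
#'   array_id, probe_id, channel, gene, control_flag, fg, bg), `design`
#'   (data.frame: array_id, channel, condition, replicate), and `truth` (list
#'   with `regulation`, `coordination`, `expression` data.frames), plus the
#'   `config`.
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be built with sim_config()", call. = FALSE)
  }
  if (config$n_replicates %% 2 != 0) {
    stop("n_replicates must be even: two replicates of the same condition ",
         "are co-hybridized per array", call. = FALSE)
  }
  set.seed(config$seed)
  genes <- config$gene_names
  conds <- config$conditions
  nrep <- config$n_replicates
  channels <- names(config$label_bias_factors)

  ## per-gene baseline and biological variability
  log_mu <- stats::runif(config$n_genes,
                         config$expression_log_mean_range[1],
                         config$expression_log_mean_range[2])
  cv <- stats::runif(config$n_genes,
                     config$biological_cv_range[1],
                     config$biological_cv_range[2])
  log_sd <- sqrt(log(1 + cv^2))
  names(log_mu) <- names(log_sd) <- genes

  ## condition log-means with planted regulation applied multiplicatively
  cond_log_mu <- matrix(log_mu, config$n_genes, length(conds),
                        dimnames = list(genes, conds))
  plan <- config$planted_regulation
  if (nrow(plan) > 0) {
    cmp <- parse_comparison(plan$comparison)
    for (i in seq_len(nrow(plan))) {
      fc <- plan$fold_change[i]
      cond_log_mu[plan$gene[i], cmp$numerator[i]] <-
        cond_log_mu[plan$gene[i], cmp$denominator[i]] +
        sign(fc) * log(abs(fc))
    }
  }

  ## block membership: latent-factor genes get block deviations instead of
  ## independent per-gene noise
  blocks <- config$planted_correlation_blocks
  block_genes <- unlist(lapply(blocks, `[[`, "genes"))

  log_level <- array(NA_real_, dim = c(config$n_genes, length(conds), nrep),
                     dimnames = list(genes, conds, NULL))
  for (ci in seq_along(conds)) {
    dev <- matrix(stats::rnorm(config$n_genes * nrep), config$n_genes, nrep) *
      log_sd
    for (b in blocks) {
      dev[match(b$genes, genes), ] <-
        plant_coordination(block_loadings(b, conds[ci]), nrep, b$sigma2)
    }
    log_level[, ci, ] <- cond_log_mu[, ci] + dev
  }

  ## probe layout: fixed across arrays
  k <- if (config$spots_per_gene[1] == config$spots_per_gene[2]) {
    rep(config$spots_per_gene[1], config$n_genes)
  } else {
    sample(seq(config$spots_per_gene[1], config$spots_per_gene[2]),
           config$n_genes, replace = TRUE)
  }
  probe_gene <- rep(genes, k)
  probe_id <- paste0(probe_gene, "_s", unlist(lapply(k, seq_len)))
  n_gene_spots <- length(probe_id)
  n_ctrl <- ceiling(config$control_spot_fraction /
                      max(1 - config$control_spot_fraction, 1e-12) *
                      n_gene_spots)
  if (n_ctrl > 0) {
    probe_id <- c(probe_id, sprintf("CTRL_%04d", seq_len(n_ctrl)))
    probe_gene <- c(probe_gene, rep("", n_ctrl))
  }
  is_ctrl <- probe_gene == ""
  n_probes <- length(probe_id)

  ## design: arrays pair consecutive replicates of one condition
  n_arrays_per_cond <- nrep / 2
  design <- do.call(rbind, lapply(seq_along(conds), function(ci) {
    do.call(rbind, lapply(seq_len(n_arrays_per_cond), function(a) {
      data.frame(
        array_id = sprintf("A%s_%d", conds[ci], a),
        channel = channels,
        condition = conds[ci],
        replicate = c(2 * a - 1, 2 * a),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(design) <- NULL

  tech_sd <- sqrt(log(1 + config$technical_cv^2))
  bg_sdlog <- 0.3
  bg_meanlog <- log(config$background_mean) - bg_sdlog^2 / 2
  ctrl_level <- exp(mean(config$expression_log_mean_range))

  spots <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    cond <- design$condition[i]
    rep_i <- design$replicate[i]
    lvl <- numeric(n_probes)
    lvl[!is_ctrl] <- exp(log_level[probe_gene[!is_ctrl], cond, rep_i])
    lvl[is_ctrl] <- ctrl_level
    bias <- config$label_bias_factors[[design$channel[i]]]
    noise <- exp(stats::rnorm(n_probes, 0, tech_sd))
    bg <- stats::rlnorm(n_probes, bg_meanlog, bg_sdlog)
    fg <- lvl * bias * noise + bg
    data.frame(
      array_id = design$array_id[i], probe_id = probe_id,
      channel = design$channel[i], gene = probe_gene,
      control_flag = is_ctrl, fg = fg, bg = bg,
      stringsAsFactors = FALSE
    )
  }))
  rownames(spots) <- NULL

  ## force a fraction of non-control spots invalid: fg just below 2 bg
  if (config$invalid_spot_fraction > 0) {
    cand <- which(!spots$control_flag)
    n_bad <- round(config$invalid_spot_fraction * length(cand))
    if (n_bad > 0) {
      bad <- sample(cand, n_bad)
      spots$fg[bad] <- spots$bg[bad] * stats::runif(n_bad, 0.5, 1.95)
    }
  }

  truth <- list(
    regulation = regulation_truth(config, genes),
    coordination = coordination_truth(config),
    expression = data.frame(
      gene = rep(genes, length(conds)),
      condition = rep(conds, each = config$n_genes),
      true_mean = exp(as.vector(cond_log_mu)),
      stringsAsFactors = FALSE
    )
  )

  structure(list(spots = spots, design = design, truth = truth,
                 config = config),
            class = "sim_experiment")
}

regulation_truth <- function(config, genes) {
  plan <- config$planted_regulation
  cmps <- unique(plan$comparison)
  if (length(cmps) == 0) cmps <- character(0)
  out <- do.call(rbind, lapply(cmps, function(cm) {
    data.frame(gene = genes, comparison = cm,
               fold_change = 1, regulated = FALSE,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(gene = character(0), comparison = character(0),
                      fold_change = numeric(0), regulated = logical(0)))
  }
  idx <- match(paste(plan$gene, plan$comparison),
               paste(out$gene, out$comparison))
  out$fold_change[idx] <- plan$fold_change
  out$regulated[idx] <- TRUE
  out
}

coordination_truth <- function(config) {
  rows <- list()
  for (b in config$planted_correlation_blocks) {
    g <- b$genes
    if (length(g) < 2) next
    pair_idx <- utils::combn(length(g), 2)
    for (cond in config$conditions) {
      l <- block_loadings(b, cond)
      r <- planted_correlation(l[pair_idx[1, ]], l[pair_idx[2, ]], b$sigma2)
      rows[[length(rows) + 1]] <- data.frame(
        gene_a = g[pair_idx[1, ]], gene_b = g[pair_idx[2, ]],
        condition = cond, r_planted = r,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      condition = character(0), r_planted = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Parse comparison labels of the form "B_vs_A" or "B:A"
#'
#' @param x Character vector of comparison labels.
#' @return Data frame with columns `numerator` and `denominator`.
#' @keywords internal
parse_comparison <- function(x) {
  parts <- strsplit(x, "_vs_|:", perl = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    stop("malformed comparison label: ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  }
  data.frame(numerator = vapply(parts, `[`, "", 1),
             denominator = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}
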