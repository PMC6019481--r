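# Shared fixtures: all synthetic, built in code at test time.

# A minimal hand-written spot table: one array, one channel, `n` gene spots
# with chosen fg/bg, plus optional control spots.
spot_table <- function(fg, bg, gene = sprintf("G%02d", seq_along(fg)),
                       probe_id = paste0(gene, "_s1"),
                       array_id = "A1", channel = "Cy3",
                       control_flag = FALSE) {
  data.frame(array_id = array_id, probe_id = probe_id, channel = channel,
             gene = gene, control_flag = control_flag, fg = fg, bg = bg,
             stringsAsFactors = FALSE)
}

# Small simulation config for fast pipeline-level tests.
quick_config <- function(seed, n_genes = 150, ...) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  sim_config(n_genes = n_genes, gene_names = genes, seed = seed, ...)
}

# Config matching the parameter-recovery study conditions: planted |FC| = 3,
# biological CV <= 0.2, 4 replicates, no coordination blocks.
recovery_config <- function(seed, n_genes = 150, n_planted = 30) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  plan <- data.frame(gene = genes[seq_len(n_planted)],
                     comparison = "COS_vs_CON",
                     fold_change = 3 * rep(c(1, -1), length.out = n_planted))
  sim_config(n_genes = n_genes, gene_names = genes,
             biological_cv_range = c(0.05, 0.2),
             planted_regulation = plan,
             planted_correlation_blocks = list(),
             seed = seed)
}

# Config with strong planted coordination blocks (|rho| = 0.98 on the log
# scale) and quiet technical noise so the planted correlation is what the
# coordination stage sees. The universe is kept large enough (150 genes)
# that per-sample normalization factors are essentially independent of any
# one block; with few filler genes the factor tracks the latent factor and
# attenuates the planted correlation.
coordination_config <- function(seed, n_genes = 150) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  sigma2 <- 1 * (1 / 0.98 - 1)  # loadings 1 => planted |r| = 0.98
  blocks <- list(
    list(genes = genes[1:8], loadings = 1, sigma2 = sigma2),
    list(genes = genes[9:16], loadings = rep(c(1, -1), 4), sigma2 = sigma2)
  )
  sim_config(n_genes = n_genes, gene_names = genes,
             planted_regulation = data.frame(gene = character(0),
                                             comparison = character(0),
                                             fold_change = numeric(0)),
             planted_correlation_blocks = blocks,
             technical_cv = 0.02, spots_per_gene = 2,
             invalid_spot_fraction = 0, seed = seed)
}

normalized_experiment <- function(config) {
  exp <- simulate_experiment(config)
  list(exp = exp, em = normalize_spots(exp$spots, exp$design))
}

unordered_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
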