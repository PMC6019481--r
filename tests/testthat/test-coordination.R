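test_that("unordered pair enumeration matches the closed form", {
  expect_equal(n_gene_pairs(2), 1)
  expect_equal(n_gene_pairs(12710), 80765695)
})

test_that("the critical correlation comes from the exact t transform", {
  expect_equal(r_critical(4), 0.95, tolerance = 1e-4)
  # matches qt directly
  tc <- qt(0.975, 2)
  expect_equal(r_critical(4), tc / sqrt(tc^2 + 2))
  # grows as replicates shrink
  expect_gt(r_critical(4), r_critical(10))
  expect_error(r_critical(2), ">= 3")
})

test_that("S/A/I/U classification is exclusive and exhaustive", {
  expect_equal(classify_coordination(0.96, 4), "S")
  expect_equal(classify_coordination(-0.96, 4), "A")
  expect_equal(classify_coordination(0, 4), "I")
  expect_equal(classify_coordination(0.25, 4), "I")
  expect_equal(classify_coordination(0.5, 4), "U")
  expect_equal(classify_coordination(-0.94, 4), "U")
  r <- seq(-1, 1, by = 0.01)
  cls <- classify_coordination(r, 4)
  expect_true(all(cls %in% c("S", "A", "I", "U")))
})

test_that("pairwise coordination enumerates each unordered pair once", {
  res <- normalized_experiment(coordination_config(51))
  e <- coordination_edges(res$em, "CON")
  g <- complete_genes(res$em, "CON")
  expect_equal(nrow(e), n_gene_pairs(length(g)))
  expect_true(all(e$gene_a < e$gene_b))
  expect_false(anyDuplicated(paste(e$gene_a, e$gene_b)) > 0)
  expect_true(all(abs(e$r) <= 1, na.rm = TRUE))
  # classification invariants on the emitted edges
  s <- e$class == "S" & !is.na(e$class)
  a <- e$class == "A" & !is.na(e$class)
  expect_true(all(e$r[s] > 0 & e$p_sig[s] < 0.05))
  expect_true(all(e$r[a] < 0 & e$p_sig[a] < 0.05))
  expect_true(all(abs(e$r[e$class == "I" & !is.na(e$class)]) <= 0.25))
})

test_that("correlation is invariant to positive affine transforms", {
  x <- c(1, 2, 3, 4)
  expect_equal(cor(x, 2 * x + 1), 1)
  m <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 2, 4, byrow = TRUE)
  expect_equal(cor(m[1, ], m[2, ]), 1)
  expect_equal(cor(m[1, ], rev(m[2, ])), -1)
})

test_that("cross-set percentages cover computable cross pairs only", {
  edges <- data.frame(
    gene_a = c("A1", "A1", "A2", "A2", "A1"),
    gene_b = c("B1", "B2", "B1", "B2", "A2"),
    condition = "CON",
    r = c(0.99, 0.97, -0.99, 0.1, 0.99), n = 4,
    p_sig = 0.01,
    class = c("S", "S", "A", "I", "S"),
    stringsAsFactors = FALSE)
  pct <- cross_set_percentages(c("A1", "A2"), c("B1", "B2"), edges)
  expect_equal(pct$n_pairs, 4)  # the within-set A1-A2 edge is excluded
  expect_equal(pct$pct_s, 50)
  expect_equal(pct$pct_a, 25)
  expect_equal(pct$pct_i, 25)
  expect_lte(pct$pct_s + pct$pct_a + pct$pct_i, 100)
  # genes in both sets are left to the common-gene layer
  pct2 <- cross_set_percentages(c("A1", "A2", "B1"), c("B1", "B2"), edges)
  expect_equal(pct2$n_pairs, 2)
  expect_error(cross_set_percentages("A1", "Zz", edges), "no computable")
})

test_that("switch detection equals the brute-force class comparison", {
  res <- normalized_experiment(coordination_config(52, n_genes = 40))
  g <- complete_genes(res$em, c("CEN", "CES"))
  e1 <- coordination_edges(res$em, "CEN", genes = g)
  e2 <- coordination_edges(res$em, "CES", genes = g)
  sw <- detect_switches(e1, e2)

  # oracle: recompute classes pair by pair from the matrix and diff the sets
  cols1 <- res$em$samples$sample[res$em$samples$condition == "CEN"]
  cols2 <- res$em$samples$sample[res$em$samples$condition == "CES"]
  oracle <- list()
  for (i in seq_len(length(g) - 1)) {
    for (j in seq(i + 1, length(g))) {
      v1 <- log(res$em$values[c(g[i], g[j]), cols1])
      v2 <- log(res$em$values[c(g[i], g[j]), cols2])
      c1 <- classify_coordination(cor(v1[1, ], v1[2, ]), 4)
      c2 <- classify_coordination(cor(v2[1, ], v2[2, ]), 4)
      if (!is.na(c1) && !is.na(c2) && c1 != c2) {
        oracle[[length(oracle) + 1]] <-
          data.frame(gene_a = g[i], gene_b = g[j], from_class = c1,
                     to_class = c2, stringsAsFactors = FALSE)
      }
    }
  }
  oracle <- do.call(rbind, oracle)
  expect_equal(nrow(sw), nrow(oracle))
  expect_setequal(paste(sw$gene_a, sw$gene_b, sw$from_class, sw$to_class),
                  paste(oracle$gene_a, oracle$gene_b, oracle$from_class,
                        oracle$to_class))
  # S in both conditions is not a switch
  stable <- merge(e1[e1$class == "S", c("gene_a", "gene_b")],
                  e2[e2$class == "S", c("gene_a", "gene_b")])
  if (nrow(stable) > 0) {
    expect_false(any(paste(stable$gene_a, stable$gene_b) %in%
                       paste(sw$gene_a, sw$gene_b)))
  }
  expect_error(detect_switches(e1, e2[-1, ]), "pair universes")
})

test_that("flipping half a latent-factor block plants S-to-A switches", {
  genes <- sprintf("G%03d", 1:150)
  blocks <- list(list(genes = genes[1:8], loadings = 1,
                      sigma2 = 1 / 0.98 - 1,
                      flip_genes = genes[1:4], flip_conditions = "CES"))
  cfg <- sim_config(n_genes = 150, gene_names = genes,
                    planted_regulation = data.frame(
                      gene = character(0), comparison = character(0),
                      fold_change = numeric(0)),
                    planted_correlation_blocks = blocks,
                    technical_cv = 0.02, invalid_spot_fraction = 0,
                    spots_per_gene = 2, seed = 53)
  # the generated truth flips exactly the cross-half pairs
  exp <- simulate_experiment(cfg)
  tr <- exp$truth$coordination
  flipped <- tr$r_planted[tr$condition == "CES"] *
    tr$r_planted[tr$condition == "CEN"] < 0
  cross_half <- xor(tr$gene_a[tr$condition == "CES"] %in% genes[1:4],
                    tr$gene_b[tr$condition == "CES"] %in% genes[1:4])
  expect_equal(flipped, cross_half)

  em <- normalize_spots(exp$spots, exp$design)
  g <- complete_genes(em, c("CEN", "CES"))
  e1 <- coordination_edges(em, "CEN", genes = g)
  e2 <- coordination_edges(em, "CES", genes = g)
  sw <- detect_switches(e1, e2)
  key <- unordered_key(sw$gene_a[sw$switch_type == "S_to_A"],
                       sw$gene_b[sw$switch_type == "S_to_A"])
  cross_pairs <- expand.grid(a = genes[1:4], b = genes[5:8],
                             stringsAsFactors = FALSE)
  cross_key <- unordered_key(cross_pairs$a, cross_pairs$b)
  # most planted cross-half pairs flip S -> A (sampling noise at n = 4
  # keeps a few below the significance threshold)
  expect_gt(mean(cross_key %in% key), 0.5)
  # unplanted S -> A switches arise only at the chance rate of two
  # opposite-signed significant correlations (about (alpha/2)^2 per pair)
  expect_lt(sum(!key %in% cross_key) / n_gene_pairs(length(g)), 0.005)
})

test_that("two-pathway networks run through the common-gene layer", {
  edges <- data.frame(
    gene_a = c("E1", "C1", "E1", "C1"),
    gene_b = c("C1", "N1", "N1", "N2"),
    condition = "CEN", r = c(0.99, -0.99, 0.99, 0.4), n = 4, p_sig = 0.01,
    class = c("S", "A", "S", "U"), stringsAsFactors = FALSE)
  # empty common-gene set: empty network
  net0 <- build_network(c("E1"), c("N1"), character(0), edges)
  expect_equal(nrow(net0$edges), 0)
  # one common gene S-linked to the first set and A-linked to the second:
  # two edges; the direct E1-N1 edge bypassing the layer is not emitted,
  # nor is the U-class edge
  reg <- data.frame(gene = c("E1", "C1", "N1"), comparison = "B_vs_A",
                    x = c(2, 1, -2), cut = 1.3, p = 0.01,
                    call = c("up", "none", "down"),
                    onoff = "expressed_both", stringsAsFactors = FALSE)
  net <- build_network(c("E1", "C1"), c("N1", "N2", "C1"), "C1", edges,
                       regulation = reg)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$layer_pair, c("A-CG", "CG-B"))
  expect_equal(net$nodes$call[net$nodes$gene == "E1"], "up")
  expect_equal(net$nodes$call[net$nodes$gene == "N1"], "down")
  expect_equal(net$nodes$layer[net$nodes$gene == "C1"], "CG")
  expect_warning(build_network("E1", "N1", "Zz", edges), "absent")
})

test_that("the switch census groups switches per gene", {
  sw <- data.frame(gene_a = c("Hub", "Hub", "Hub", "X"),
                   gene_b = c("P1", "P2", "P3", "Hub"),
                   from_class = c("S", "S", "A", "S"),
                   to_class = c("A", "A", "S", "A"),
                   switch_type = c("S_to_A", "S_to_A", "A_to_S", "S_to_A"),
                   stringsAsFactors = FALSE)
  cen <- switch_census(sw)
  expect_equal(cen$gene[1], "Hub")
  expect_equal(cen$n_s_to_a[1], 3)
  expect_equal(cen$n_a_to_s[1], 1)
})
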