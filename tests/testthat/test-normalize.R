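test_that("spot validity keeps exactly the non-control spots with fg >= 2 bg", {
  expect_equal(nrow(validate_spots(spot_table(fg = 100, bg = 50))), 1)
  expect_equal(nrow(validate_spots(spot_table(fg = 99, bg = 50))), 0)

  ratios <- c(0.5, 1, 1.5, 1.9, 2.0, 2.1, 3, 4, 5, 10)
  tab <- spot_table(fg = 100 * ratios, bg = 100)
  kept <- validate_spots(tab)
  expect_equal(nrow(kept), 6)
  expect_true(all(kept$fg / kept$bg >= 2))
  expect_equal(attr(kept, "retention")$n_invalid, 4)

  # control spots are dropped regardless of their ratio
  ctrl <- spot_table(fg = 1000, bg = 10, control_flag = TRUE, gene = "")
  expect_equal(nrow(validate_spots(rbind(tab, ctrl))), 6)

  # idempotence
  expect_equal(validate_spots(kept), kept, ignore_attr = TRUE)

  expect_error(validate_spots(spot_table(fg = -1, bg = 0)), "negative")
})

test_that("within-label normalization anchors each (array,label) median at 1", {
  tab <- spot_table(fg = c(2, 4, 8), bg = 0)
  expect_equal(normalize_within_label(tab)$value, c(0.5, 1, 2))

  same <- spot_table(fg = rep(7, 5), bg = 2)
  expect_equal(normalize_within_label(same)$value, rep(1, 5))

  # even-sized group: midpoint median convention
  even <- spot_table(fg = 1:4, bg = 0)
  expect_equal(normalize_within_label(even)$value, c(0.4, 0.8, 1.2, 1.6))

  # groups are independent per (array, label)
  two <- rbind(spot_table(fg = c(2, 4, 8), bg = 0, array_id = "A1"),
               spot_table(fg = c(20, 40, 80), bg = 0, array_id = "A2"))
  v <- normalize_within_label(two)$value
  expect_equal(v[1:3], v[4:6])
  expect_equal(as.numeric(tapply(v, two$array_id, median)), c(1, 1))
})

test_that("redundancy collapsing averages spots per gene per sample", {
  design <- data.frame(array_id = "A1", channel = "Cy3",
                       condition = "CON", replicate = 1)
  spots <- spot_table(fg = 1, bg = 0, gene = c("Ga", "Ga", "Ga", "Gb"),
                      probe_id = c("Ga_s1", "Ga_s2", "Ga_s3", "Gb_s1"))
  spots$value <- c(1.0, 1.2, 0.8, 2.0)
  em <- collapse_redundancy(spots, design)
  expect_equal(em$values["Ga", "CON_r1"], 1.0)
  expect_equal(em$values["Gb", "CON_r1"], 2.0)  # mean of a singleton
  expect_true(all(em$mask))

  # missing gene in a sample: mask false, value NA
  design2 <- rbind(design, data.frame(array_id = "A1", channel = "Cy5",
                                      condition = "CON", replicate = 2))
  spots2 <- spots
  spots2$channel <- "Cy5"
  spots2 <- spots2[spots2$gene != "Gb", ]
  em2 <- collapse_redundancy(rbind(spots, spots2), design2)
  expect_false(em2$mask["Gb", "CON_r2"])
  expect_true(is.na(em2$values["Gb", "CON_r2"]))

  # order independence: permuting spots changes nothing
  perm <- spots[sample(nrow(spots)), ]
  expect_equal(collapse_redundancy(perm, design)$values, em$values)
})

test_that("iterative renormalization stops at once on aligned data", {
  # every sample already identical: the fixed point, one pass, zero change
  v <- c(1, 2, 4, 8, 16)
  samples <- data.frame(sample = c("CON_r1", "CON_r2", "COS_r1", "COS_r2"),
                        condition = rep(c("CON", "COS"), each = 2),
                        replicate = c(1, 2, 1, 2))
  em0 <- structure(list(
    values = matrix(v, 5, 4, dimnames = list(paste0("G", 1:5),
                                             samples$sample)),
    probe_values = matrix(v, 5, 4, dimnames = list(paste0("G", 1:5, "_s1"),
                                                   samples$sample)),
    probe_gene = setNames(paste0("G", 1:5), paste0("G", 1:5, "_s1")),
    samples = samples), class = "expr_matrix")
  em0$mask <- !is.na(em0$values)
  em1 <- iterative_renormalize(em0)
  expect_equal(attr(em1, "iterations"), 1)
  expect_equal(attr(em1, "final_delta"), 0)
  expect_error(iterative_renormalize(em0, tol = 0, max_iter = 3),
               "did not converge")
})

test_that("rescaling one sample is undone by iterative renormalization", {
  res <- normalized_experiment(quick_config(22, n_genes = 80))
  em0 <- collapse_redundancy(
    normalize_within_label(validate_spots(res$exp$spots)), res$exp$design)
  base <- iterative_renormalize(em0)
  scaled <- em0
  scaled$values[, 3] <- scaled$values[, 3] * 7
  scaled$probe_values[, 3] <- scaled$probe_values[, 3] * 7
  redone <- iterative_renormalize(scaled)
  ratio_of_ratios <- pathprotect:::cross_condition_ratios(redone) /
    pathprotect:::cross_condition_ratios(base)
  expect_lt(mean(abs(ratio_of_ratios - 1), na.rm = TRUE), 0.05)
})

test_that("scaling all fluorescence of one (array,label) leaves results unchanged", {
  exp <- simulate_experiment(quick_config(23, n_genes = 60))
  em_a <- normalize_spots(exp$spots, exp$design)
  scaled <- exp$spots
  pick <- scaled$array_id == scaled$array_id[1] & scaled$channel == "Cy3"
  scaled$fg[pick] <- scaled$fg[pick] * 13
  scaled$bg[pick] <- scaled$bg[pick] * 13
  em_b <- normalize_spots(scaled, exp$design)
  expect_equal(em_b$values, em_a$values, tolerance = 1e-9)
})

test_that("condition statistics pool biological and technical variability", {
  res <- normalized_experiment(quick_config(24, n_genes = 50))
  st <- res$em$stats
  expect_true(all(st$cv >= 0, na.rm = TRUE))
  expect_true(all(st$mu > 0, na.rm = TRUE))
  expect_true(all(st$n_valid <= st$n_replicates))
  # quantified means valid in at least n - 1 replicates
  expect_equal(st$quantified, st$n_valid >= st$n_replicates - 1)
  # folding the per-replicate standard error in can only increase the CV
  vals <- res$em$values
  cols <- res$em$samples$sample[res$em$samples$condition == "CON"]
  g <- st$gene[st$condition == "CON" & st$n_valid == 4][1]
  bio_cv <- sd(vals[g, cols]) / mean(vals[g, cols])
  expect_gte(st$cv[st$gene == g & st$condition == "CON"] + 1e-12, bio_cv)
})
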