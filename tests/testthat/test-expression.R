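test_that("read-support thresholding uses strict counts and group fractions", {
  # 5 HC, 5 UC libraries; g1: exactly 10 reads everywhere (never >10);
  # g2: 11 reads in exactly 40% of UC libraries; g3: all zero
  vals <- cbind(g1 = rep(10, 10),
                g2 = c(rep(0, 5), 11, 11, 0, 0, 0),
                g3 = rep(0, 10),
                g4 = rep(100, 10))
  counts <- toy_counts(vals, rep(c("HC", "UC"), each = 5))
  kept <- threshold_genes(counts, min_reads = 10, min_frac = 0.40)
  expect_false("g1" %in% kept)   # 10 is not > 10
  expect_true("g2" %in% kept)    # 2/5 = 40% of UC meets >= min_frac
  expect_false("g3" %in% kept)
  expect_true("g4" %in% kept)
  expect_error(threshold_genes(counts, group_by = "nope"), "group key")
})

test_that("thresholding is monotone in min_reads", {
  sc <- small_cohort()
  k10 <- threshold_genes(sc$counts, min_reads = 10)
  k50 <- threshold_genes(sc$counts, min_reads = 50)
  expect_true(all(k50 %in% k10))
})

test_that("TPM normalization matches hand-computed rates", {
  vals <- cbind(g1 = c(100, 40), g2 = c(200, 40))
  counts <- toy_counts(vals, c("HC", "HC"))
  tpm <- tpm_normalize(counts, c(g1 = 1000, g2 = 2000))
  # sample 1: rates 100 and 100 -> 500,000 each
  expect_equal(unname(tpm$values[1, ]), c(5e5, 5e5))
  expect_equal(unname(rowSums(tpm$values)), c(1e6, 1e6))
})

test_that("TPM is depth-invariant and a single gene saturates at 1e6", {
  vals <- cbind(g1 = c(10, 20), g2 = c(30, 60))
  counts <- toy_counts(vals, c("HC", "HC"))
  tpm <- tpm_normalize(counts, c(g1 = 500, g2 = 1500))
  expect_equal(tpm$values[1, ], tpm$values[2, ])  # sample 2 = 2x depth

  single <- tpm_normalize(counts, c(g1 = 500, g2 = 1500), retained = "g1")
  expect_equal(unname(single$values[, "g1"]), c(1e6, 1e6))

  zero <- toy_counts(cbind(g1 = c(0, 5), g2 = c(0, 5)), c("HC", "HC"))
  expect_error(tpm_normalize(zero, c(g1 = 100, g2 = 100)), "S01")
})

test_that("log transform is log2(TPM + 1)", {
  vals <- cbind(g1 = c(0, 1), g2 = c(1, 3), g3 = c(3, 0))
  tpm <- toy_counts(vals, c("HC", "HC"))
  tpm$scale <- "TPM"
  lt <- log_transform(tpm)
  expect_equal(unname(lt$values[, "g1"]), c(0, 1))
  expect_equal(unname(lt$values[1, c("g2", "g3")]), c(1, 2))
  expect_equal(lt$scale, "logTPM")
})

test_that("tissue specificity requires presence in one tissue only", {
  vals <- cbind(g_rect = c(0, 0, 1, 1), g_both = c(1, 1, 1, 1),
                g_edge = c(0, 0, 0.5, 0.5))
  rownames(vals) <- sprintf("S%02d", 1:4)
  samples <- data.frame(sample_id = rownames(vals),
                        tissue = c("colon", "colon", "rectum", "rectum"))
  tpm <- expression_matrix(vals, "TPM", samples)
  sets <- tissue_specific_genes(tpm, min_tpm = 0.5, min_frac = 0.30)
  expect_equal(sets$rectum, "g_rect")
  expect_false("g_both" %in% unlist(sets))
  expect_false("g_edge" %in% unlist(sets))  # 0.5 is not > 0.5
  expect_length(intersect(sets$colon, sets$rectum), 0)
})

test_that("normalized SD is sd/mean and scale-invariant", {
  vals <- cbind(g_const = c(2, 2), g_var = c(1, 3), g_scaled = c(10, 30))
  expr <- toy_counts(vals, c("HC", "HC"))
  expr$scale <- "logTPM"
  nsd <- normalized_sd(expr)
  expect_equal(unname(nsd["g_const"]), 0)
  expect_equal(unname(nsd["g_var"]), sqrt(2) / 2)
  expect_equal(unname(nsd["g_scaled"]), unname(nsd["g_var"]))

  withzero <- toy_counts(cbind(g0 = c(0, 0), g1 = c(1, 2)), c("HC", "HC"))
  withzero$scale <- "logTPM"
  expect_warning(nsd0 <- normalized_sd(withzero), "zero-mean")
  expect_false("g0" %in% names(nsd0))
})

test_that("biotype statistics detect planted distributional differences", {
  sc <- small_cohort()
  ann <- sc$cohort$annotation
  genes <- colnames(sc$logtpm$values)
  # KS edge cases on hand-made connectivity vectors
  kim_same <- setNames(rep(seq(0, 1, length.out = 10), 20)[seq_along(genes)],
                       genes)
  bs <- biotype_stats(sc$logtpm, ann, kim = kim_same)
  expect_true(bs$ks_kim$statistic >= 0 && bs$ks_kim$statistic <= 1)
  # disjoint supports give KS statistic 1
  is_lnc <- ann$biotype[match(genes, ann$gene_id)] == "lncRNA"
  kim_disjoint <- setNames(ifelse(is_lnc, runif(length(genes)),
                                  2 + runif(length(genes))), genes)
  bs2 <- biotype_stats(sc$logtpm, ann, kim = kim_disjoint)
  expect_equal(bs2$ks_kim$statistic, 1)
  # the generator's lncRNA expression shift is recovered by the t test
  expect_lt(bs$t_mean_expression$mean_lncRNA,
            bs$t_mean_expression$mean_protein_coding)
})

test_that("biotype statistics need both biotypes", {
  sc <- small_cohort()
  ann <- sc$cohort$annotation
  ann$biotype <- "lncRNA"
  expect_error(biotype_stats(sc$logtpm, ann), "both biotypes")
})
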