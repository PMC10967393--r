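test_that("cohort generation is byte-identical under a fixed seed", {
  cc <- cohort_config(n_patients = 15, n_genes = 120, n_modules = 2,
                      module_sizes = 25, seed = 7)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a$counts, b$counts)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$modules, b$truth$modules)
})

test_that("cohort config rejects inconsistent settings", {
  expect_error(cohort_config(n_genes = 100, n_modules = 2,
                             module_sizes = 80), "exceeds")
  expect_error(cohort_config(diseases = c(HC = 0.5, UC = 0.2, CD = 0.2)),
               "sum to 1")
  expect_error(cohort_config(frac_lncRNA = 1.5), "frac_lncRNA")
})

test_that("counts are nonnegative integers with planted structure recorded", {
  coh <- generate_cohort(cohort_config(n_patients = 12, n_genes = 100,
                                       n_modules = 2, module_sizes = 20,
                                       seed = 3))
  expect_true(all(coh$counts >= 0))
  expect_true(is.integer(coh$counts))
  expect_setequal(names(coh$truth$modules), coh$annotation$gene_id)
  expect_equal(sum(coh$truth$modules != "grey"), 40)
  expect_true(all(coh$annotation$start < coh$annotation$end))
})

test_that("null configuration yields near-zero gene-gene correlations", {
  cc <- cohort_config(n_patients = 60, n_genes = 150, n_modules = 1,
                      module_sizes = 30, module_loading = 0,
                      trait_effects = list(numeric(0)),
                      dropout_slope = 0.0001, seed = 19)
  coh <- generate_cohort(cc)
  lt <- log2(1 + coh$counts)
  r <- cor(lt[, apply(lt, 2, sd) > 0])
  off <- r[upper.tri(r)]
  expect_lt(abs(mean(off)), 3 / sqrt(nrow(lt)))
})

test_that("lncRNAs are simulated with lower expression than coding genes", {
  coh <- generate_cohort(cohort_config(n_patients = 25, n_genes = 2000,
                                       n_modules = 2, module_sizes = 50,
                                       lnc_expression_shift = -2, seed = 5))
  counts <- expression_matrix(coh$counts, "counts", coh$samples)
  lengths <- setNames(coh$annotation$length, coh$annotation$gene_id)
  tpm <- tpm_normalize(counts, lengths)
  mu <- colMeans(log2(tpm$values + 1))
  is_lnc <- coh$annotation$biotype == "lncRNA"
  tt <- t.test(mu[is_lnc], mu[!is_lnc], alternative = "less")
  expect_lt(tt$p.value, 0.01)
})

test_that("snp catalog generation is seeded and validates module labels", {
  coh <- generate_cohort(cohort_config(n_patients = 10, n_genes = 200,
                                       n_modules = 2, module_sizes = 30,
                                       seed = 2))
  s1 <- generate_snp_catalog(coh$annotation, n_snps = 100, seed = 9)
  s2 <- generate_snp_catalog(coh$annotation, n_snps = 100, seed = 9)
  expect_identical(s1, s2)
  expect_error(generate_snp_catalog(coh$annotation, "nope", coh$truth),
               "unknown module")
  expect_error(generate_snp_catalog(coh$annotation, "1", coh$truth,
                                    frac_uc = 0.5, frac_cd = 0.5,
                                    frac_shared = 0.5), "sum to 1")
})

test_that("fully planted SNPs make every module gene adjacent", {
  coh <- generate_cohort(cohort_config(n_patients = 10, n_genes = 200,
                                       n_modules = 2, module_sizes = 30,
                                       seed = 2))
  snps <- generate_snp_catalog(coh$annotation, "1", coh$truth,
                               n_snps = 400, excess_rate = 1, seed = 4)
  adj <- snp_adjacent_genes(coh$annotation, snps)
  mod1 <- names(coh$truth$modules)[coh$truth$modules == "1"]
  expect_equal(mean(adj$adjacent[mod1]), 1.0)
})

test_that("screen counts are seeded, validated, and centered under the null", {
  s1 <- generate_screen(40, 6, 30, seed = 8)
  s2 <- generate_screen(40, 6, 30, seed = 8)
  expect_identical(s1, s2)
  expect_error(generate_screen(10, depth = 0), "depth")
  expect_error(generate_screen(10, guides_per_gene = 1,
                               regulators = c(LNC0001 = 1)), "guides_per_gene")

  null_screen <- generate_screen(100, 6, 100, depth = 1e6, seed = 12)
  lfc <- screen_log2fc(null_screen, "TNF_hi")
  expect_lt(abs(median(lfc)), 0.05)
})

test_that("a near-infinite screen effect puts the gene's guides at the top", {
  scr <- generate_screen(50, 6, 50, regulators = c(LNC0010 = 10),
                         guide_noise_sd = 0, seed = 21)
  lfc <- screen_log2fc(scr, "TNF_hi")
  top6 <- names(sort(lfc, decreasing = TRUE))[1:6]
  expect_setequal(unique(scr$gene[match(top6, scr$sgrna)]), "LNC0010")
})
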